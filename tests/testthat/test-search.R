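test_that("Stirling numbers and the enumeration agree with brute force", {
  for (n in 3:7) {
    for (k in 2:(n - 1)) {
      oracle <- brute_force_partitions(n, k)
      expect_identical(stirling2(n, k), as.numeric(length(oracle)))
      parts <- enumerate_constrained_partitions(n, k)
      keys <- vapply(parts, format, character(1))
      expect_identical(sort(keys), sort(oracle))
    }
  }
})

test_that("constrained enumeration counts and edge cases are right", {
  # 3 free states into 2 free blocks (plus a constrained singleton)
  parts <- enumerate_constrained_partitions(4, 3, constrained = 1)
  expect_length(parts, 3L)
  expect_true(all(vapply(parts, function(p) p$block_of[1] == 1 &&
                           sum(p$block_of == 1) == 1, logical(1))))
  # free = blocks: only the identity partition
  expect_length(enumerate_constrained_partitions(5, 5), 1L)
  # infeasible block count: empty
  expect_length(enumerate_constrained_partitions(4, 6), 0L)
  # S(16, 2) = 2^15 - 1 partitions for 16 free states into 2 blocks
  it <- partition_iterator(17, 3, constrained = 1)
  expect_identical(it$size, 32767)
  cnt <- 0L
  while (!is.null(it$next_partition())) cnt <- cnt + 1L
  expect_identical(cnt, 32767L)
})

test_that("random partitions are uniform over set partitions", {
  # 4 free states into 2 blocks: S(4,2) = 7 partitions
  set.seed(101)
  N <- 1e5
  keys <- character(N)
  for (i in seq_len(N))
    keys[i] <- format(sample_random_partition(4, 2))
  tab <- table(keys)
  expect_length(tab, 7L)
  p <- 1 / 7
  se <- sqrt(p * (1 - p) / N)
  expect_true(all(abs(tab / N - p) < 3 * se))
})

test_that("random partition sampling is reproducible and validates inputs", {
  set.seed(42); a <- replicate(5, format(sample_random_partition(6, 3, 1)))
  set.seed(42); b <- replicate(5, format(sample_random_partition(6, 3, 1)))
  expect_identical(a, b)
  # blocks = free-state count: always the identity
  expect_identical(sample_random_partition(4, 4)$block_of, 1:4)
  expect_error(sample_random_partition(4, 6), "infeasible")
})

test_that("the Metropolis rule accepts downhill always and uphill at exp(-d/T)", {
  expect_true(metropolis_accept(-1, 1e-12))
  expect_true(metropolis_accept(0, 1e-12))
  expect_error(metropolis_accept(1, 0), "> 0")
  # temperature -> 0+: uphill acceptance probability vanishes
  set.seed(3)
  expect_false(any(replicate(100, metropolis_accept(1, 1e-300))))
  # Monte-Carlo calibration at delta = 1, T = 1: rate = exp(-1)
  set.seed(9)
  N <- 1e5
  acc <- sum(replicate(N, metropolis_accept(1, 1)))
  p <- exp(-1)
  expect_lt(abs(acc / N - p), 3 * sqrt(p * (1 - p) / N))
})

test_that("an enormous tolerance accepts the fully lumped model immediately", {
  m <- random_compartmental_system(6, seed = 2)
  res <- incremental_search(m, search_config("enumeration", tolerance = 1e6))
  expect_identical(res$m, 2L)
  expect_true(res$accepted)
  expect_identical(res$evaluations, 1L)
})

test_that("incremental search recovers the true block structure, all methods", {
  for (bs in list(c(3, 2), c(4, 1, 2))) {
    sys <- exactly_lumpable_system(bs, seed = 77)
    true_m <- length(bs) + 1L
    for (meth in c("enumeration", "nars", "scree-nars", "sa")) {
      res <- incremental_search(
        sys$model, search_config(meth, tolerance = 1e-4, seed = 5,
                                 nars_samples = 2000, start_m = 2))
      expect_identical(res$m, true_m)
      expect_true(res$accepted)
      expect_lte(res$ard_percent, 1e-4)
    }
  }
})

test_that("enumeration finds the exact partition as the minimum at the true m", {
  sys <- exactly_lumpable_system(c(3, 2), seed = 15)
  fe <- full_enumeration_at_m(sys$model, 3,
                              search_config("enumeration", tolerance = 1e-8))
  expect_identical(fe$best_partition$block_of, sys$partition$block_of)
  expect_lt(fe$min_ard, 1e-6)
  expect_identical(fe$space_size, stirling2(5, 2))
  expect_identical(fe$evaluations, as.integer(fe$space_size))
})

test_that("NARS covering the whole space matches the enumeration minimum", {
  m <- random_compartmental_system(6, seed = 30)
  fe <- full_enumeration_at_m(m, 3, search_config(tolerance = 1e-12))
  nr <- nars_at_m(m, 3, n_samples = 5000,
                  search_config("nars", tolerance = 1e-12, seed = 11))
  expect_equal(nr$best_ard, fe$min_ard, tolerance = 1e-9)
})

test_that("SA matches the enumeration minimum on a 7-state system, 5 seeds", {
  m <- random_compartmental_system(7, seed = 55)
  fe <- full_enumeration_at_m(m, 3, search_config(tolerance = 1e-12))
  for (seed in 1:5) {
    sr <- sa_at_m(m, 3, sa_config(max_iterations = 5000),
                  search_config("sa", tolerance = 1e-12, seed = seed))
    expect_lt(abs(sr$best_ard - fe$min_ard), 1e-9)
  }
})

test_that("SA temperature trace is geometric and the budget is honoured", {
  m <- random_compartmental_system(7, seed = 8)
  sr <- sa_at_m(m, 4, sa_config(initial_temperature = 1e4,
                                cooling_factor = 0.999,
                                max_iterations = 500),
                search_config("sa", tolerance = 1e-14, seed = 2))
  tr <- sr$trace
  expect_lte(nrow(tr), 500L)
  expect_equal(tr$temperature,
               1e4 * 0.999^(tr$iteration - 1), tolerance = 1e-12)
  expect_true(all(diff(tr$temperature) < 0))
  # best-so-far ARD is monotone non-increasing (Inf plateaus included)
  expect_identical(tr$best_ard, cummin(tr$best_ard))
})

test_that("reported ARD re-evaluates identically (internal consistency)", {
  m <- random_compartmental_system(8, seed = 3)
  for (meth in c("enumeration", "nars", "sa")) {
    res <- incremental_search(m, search_config(meth, tolerance = 0.5,
                                               seed = 4, nars_samples = 500))
    re <- evaluate_partition(m, res$partition,
                             criterion_config(tolerance = 0.5))
    if (res$ard_percent == 0) expect_lt(abs(re), 1e-12)
    else expect_equal(re, res$ard_percent, tolerance = 1e-12)
    expect_identical(res$m, res$partition$m)
    expect_true(res$ard_percent <= 0.5)
  }
})

test_that("stochastic searches are bit-reproducible under a fixed seed", {
  m <- random_compartmental_system(7, seed = 19)
  for (meth in c("nars", "sa")) {
    r1 <- incremental_search(m, search_config(meth, tolerance = 0.01,
                                              seed = 123, nars_samples = 300))
    r2 <- incremental_search(m, search_config(meth, tolerance = 0.01,
                                              seed = 123, nars_samples = 300))
    expect_identical(r1$partition$block_of, r2$partition$block_of)
    expect_identical(r1$ard_percent, r2$ard_percent)
    expect_identical(r1$evaluations, r2$evaluations)
  }
})

test_that("the worst case returns the identity model as accepted", {
  # tolerance far below anything any proper lump can achieve
  m <- random_compartmental_system(4, seed = 40)
  res <- incremental_search(m, search_config("enumeration", tolerance = 1e-13))
  expect_identical(res$m, 4L)
  expect_identical(res$ard_percent, 0)
  expect_true(res$accepted)
})

test_that("the labelled assignment count is exposed for reporting", {
  m <- random_compartmental_system(6, seed = 2)
  res <- incremental_search(m, search_config("enumeration", tolerance = 1e6))
  expect_identical(res$labeled_space, res$m^(m$n - 1))
})
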