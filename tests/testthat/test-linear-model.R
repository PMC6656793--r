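test_that("constructor enforces the model invariants", {
  K <- matrix(c(-1, 1, 0.5, -0.5), 2, 2)
  expect_error(compartmental_model(matrix(1, 2, 3), y0 = c(1, 0)), "square")
  expect_error(compartmental_model(matrix(-1, 1, 1), y0 = 1), "at least 2")
  expect_error(compartmental_model(K, y0 = c(0, 0)), "positive entry")
  expect_error(compartmental_model(K, y0 = c(-1, 1)), "nonnegative")
  expect_error(compartmental_model(K, y0 = c(1, 0), output_state = 3),
               "out of range")
  # mass creation: transfer out of state 1 exceeds what state 2 receives
  bad <- matrix(c(-1, 2, 0, -1), 2, 2)
  expect_error(compartmental_model(bad, volumes = c(1, 1), y0 = c(1, 0)),
               "mass balance")
  # bolus dosing converts mass to concentration through the state volume
  # (rates consistent with volumes 2 and 1 so the system is mass balanced)
  Kb <- matrix(c(-1, 2, 0.25, -0.5), 2, 2)
  m <- compartmental_model(Kb, volumes = c(2, 1), y0 = NULL,
                           dose = list(state = 1, amount = 10))
  expect_identical(unname(m$y0), c(5, 0))
})

test_that("build_rate_matrix encodes perfusion-limited kinetics", {
  # single tissue Q=1, V=2, Kp=1, no elimination: closed system
  tab <- data.frame(name = c("arterial", "venous", "lung", "tis"),
                    type = c("arterial", "venous", "lung", "tissue"),
                    Q = c(NA, NA, 1, 1), V = c(1.5, 3, 0.5, 2),
                    Kp = c(NA, NA, 1, 1))
  m <- build_rate_matrix(tab, dose = list(state = "arterial", amount = 1))
  A <- diag(m$volumes) %*% m$K %*% diag(1 / m$volumes)
  expect_lt(max(abs(colSums(A))), 1e-12)
  # tissue gains from arterial at Q/V and returns at Q/(V Kp)
  expect_equal(m$K["tis", "arterial"], 1 / 2)
  expect_equal(m$K["tis", "tis"], -1 / (2 * 1))

  expect_error(build_rate_matrix(rbind(tab,
    data.frame(name = "x1", type = "sub", Q = NA, V = 0.1, Kp = NA))),
    "parent")
  tab2 <- rbind(tab, data.frame(name = "x1", type = "sub", Q = NA, V = 0.1,
                                Kp = NA))
  tab2$parent <- c(NA, NA, NA, NA, "nowhere")
  tab2$k_in <- c(NA, NA, NA, NA, 0.1); tab2$k_out <- c(NA, NA, NA, NA, 0.2)
  expect_error(build_rate_matrix(tab2), "orphan sub-compartment 'x1'")

  tab$Q[4] <- -1
  expect_error(build_rate_matrix(tab), "must be positive")
})

test_that("flow balance against cardiac output is enforced", {
  tab <- random_physiology(4, seed = 11)
  tab$Q[3] <- tab$Q[3] * 1.05  # cardiac output off by 5%
  expect_error(physiological_parameters(tab), "cardiac output")
})

test_that("generated physiological systems are stable", {
  for (seed in 1:20) {
    m <- build_rate_matrix(random_physiology(sample(2:6, 1), seed),
                           dose = list(state = "arterial", amount = 1))
    ev <- eigen(m$K, only.values = TRUE)$values
    expect_lte(max(Re(ev)), 1e-10)
  }
})

test_that("matrix-exponential simulation matches closed forms and the ODE oracle", {
  # diagonal system: independent mono-exponential decay per state
  K <- diag(c(-0.7, -0.05))
  m <- compartmental_model(K, y0 = c(2, 3))
  tt <- c(0, 0.5, 1, 5, 20)
  sim <- simulate_model(m, tt)
  expect_identical(sim$trajectories[, 1], m$y0)  # t = 0 exact
  expect_equal(sim$trajectories[1, ], 2 * exp(-0.7 * tt), tolerance = 1e-12)
  expect_equal(sim$trajectories[2, ], 3 * exp(-0.05 * tt), tolerance = 1e-12)

  # 4-state random stable system vs adaptive Runge-Kutta/BDF oracle
  m4 <- random_stable_model(4, seed = 7)
  tt <- seq(0, 20, length.out = 41)
  sim4 <- simulate_model(m4, tt)
  orc <- ode_oracle(m4$K, m4$y0, tt)
  expect_equal(sim4$trajectories, orc, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(simulate_model(m4, c(1, -1)), "nonnegative")
  expect_error(simulate_model(m4, c(2, 1)), "ascending")
})

test_that("the matrix-exponential flow satisfies the semigroup property", {
  for (seed in 1:5) {
    m <- random_stable_model(5, seed)
    t1 <- runif(1, 0.1, 3); t2 <- runif(1, 0.1, 3)
    y12 <- simulate_model(m, c(0, t1 + t2))$trajectories[, 2]
    y1 <- simulate_model(m, c(0, t1))$trajectories[, 2]
    m2 <- compartmental_model(m$K, y0 = y1)
    y2 <- simulate_model(m2, c(0, t2))$trajectories[, 2]
    expect_equal(y12, y2, tolerance = 1e-10)
  }
})

test_that("closed systems conserve volume-weighted total amount", {
  tab <- random_physiology(5, seed = 3)
  tab$CL <- 0
  m <- build_rate_matrix(tab, dose = list(state = "arterial", amount = 50))
  sim <- simulate_model(m, seq(0, 100, by = 5))
  amounts <- colSums(sim$trajectories * m$volumes)
  expect_equal(amounts, rep(50, length(amounts)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("closed-form AUC matches dense quadrature", {
  m <- random_stable_model(5, seed = 13)
  auc <- auc_to_infinity(m)
  # composite quadrature on a dense grid out to many multiples of the
  # slowest timescale (Simpson refinement of the trapezoid sum)
  rates <- abs(Re(eigen(m$K, only.values = TRUE)$values))
  tt <- seq(0, 40 / min(rates), length.out = 20001L)
  y <- simulate_model(m, tt)$trajectories[m$output_state, ]
  h <- tt[2] - tt[1]
  i <- seq(2, length(y) - 1)
  quad <- h / 3 * (y[1] + y[length(y)] + sum(y[i] * ifelse(i %% 2 == 0, 4, 2)))
  expect_equal(auc, quad, tolerance = 1e-6)
})

test_that("non-decaying systems raise an infinite-AUC error", {
  # closed 2-state exchange: mass conserved, nothing leaves
  K <- matrix(c(-1, 1, 0.5, -0.5), 2, 2)
  m <- compartmental_model(K, volumes = c(1, 1), y0 = c(1, 0))
  expect_error(auc_to_infinity(m), "infinite AUC")
})

test_that("AUC quadrature fallback agrees with the linear solve", {
  # singular-by-construction: append a decoupled closed pair behind a
  # decaying observable subsystem
  K <- matrix(0, 4, 4)
  K[1:2, 1:2] <- matrix(c(-1.2, 0.4, 0.3, -0.8), 2, 2)
  K[3:4, 3:4] <- matrix(c(-0.5, 0.5, 0.2, -0.2), 2, 2)  # closed, unreached
  m <- compartmental_model(K, y0 = c(1, 0.5, 0, 0), output_state = 1)
  msolve <- compartmental_model(K[1:2, 1:2], y0 = c(1, 0.5), output_state = 1)
  expect_equal(auc_to_infinity(m), auc_to_infinity(msolve), tolerance = 1e-6)
})
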