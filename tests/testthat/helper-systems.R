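# Small system builders and independent oracles shared across test files.

# random stable rate matrix in the amount basis: off-diagonal transfer rates
# log-uniform, diagonal = -(column sum + elimination from state 1)
random_stable_K <- function(n, seed, elim = 0.5) {
  set.seed(seed)
  K <- matrix(10^runif(n * n, -1.5, 0.5), n, n)
  diag(K) <- 0
  diag(K) <- -colSums(K)
  K[1, 1] <- K[1, 1] - elim
  K
}

# closed system: zero column sums (mass conserved in the K basis)
random_closed_K <- function(n, seed) random_stable_K(n, seed, elim = 0)

random_stable_model <- function(n, seed, elim = 0.5) {
  set.seed(seed + 1000)
  y0 <- runif(n)
  compartmental_model(random_stable_K(n, seed, elim), y0 = y0)
}

# independent ODE oracle: adaptive lsoda integration of dy/dt = K y
ode_oracle <- function(K, y0, times, rtol = 1e-11, atol = 1e-12) {
  out <- deSolve::lsoda(y = y0, times = times,
                        func = function(t, y, p) list(as.numeric(K %*% y)),
                        rtol = rtol, atol = atol)
  t(unname(out[, -1, drop = FALSE]))
}

# brute-force set-partition oracle: canonicalised labelled assignments of
# n items into exactly k nonempty blocks, as unique label strings
brute_force_partitions <- function(n, k) {
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  keys <- apply(grid, 1, function(a) {
    if (length(unique(a)) != k) return(NA_character_)
    paste(match(a, unique(a)), collapse = "-")
  })
  unique(keys[!is.na(keys)])
}

# uniformly random valid physiological parameter table
random_physiology <- function(n_tissues, seed) {
  set.seed(seed)
  Q <- 10^runif(n_tissues, -1, 0.5)
  data.frame(
    name = c("arterial", "venous", "lung", paste0("tis", seq_len(n_tissues))),
    type = c("arterial", "venous", "lung", rep("tissue", n_tissues)),
    Q = c(NA, NA, sum(Q), Q),
    V = 10^runif(n_tissues + 3, -0.5, 1),
    Kp = c(NA, NA, 10^runif(1, -0.5, 0.8), 10^runif(n_tissues, -0.5, 1)),
    CL = c(0, 0, 0, 10^runif(1, -1, 0), rep(0, n_tissues - 1)))
}
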