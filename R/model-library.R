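#' Bundled 17-state fentanyl-like PBPK topology
#'
#' A whole-body perfusion-limited model with the classic 17-state structure
#' used in human fentanyl PBPK work: arterial and venous blood, lung, nine
#' perfused tissues (liver, spleen, gut, brain, heart, kidney, muscle, skin,
#' adipose, rest-of-body), an extra first-order sub-compartment in the liver
#' (`L_cpt_1`) and spleen (`S_cpt_1`), two in the gut (`G_cpt_1`, `G_cpt_2`),
#' spleen and gut draining portally through the liver, the liver as the only
#' site of elimination, and a 750 µg bolus into arterial blood, the output
#' state. Time is in minutes, volumes in litres, amounts in micrograms.
#'
#' The numeric parameter values are a synthetic placeholder set: realistic
#' adult human physiology with plausible partition coefficients for a
#' lipophilic opioid, shipped so the topology is runnable end-to-end. They
#' are not a transcription of any published drug-specific parameterisation;
#' the model's `provenance` field is `"synthetic-placeholder"` and quantities
#' computed from it characterise this parameter set only.
#'
#' @return a 17-state [compartmental_model()] with
#'   `provenance == "synthetic-placeholder"`.
#' @examples
#' m <- fentanyl_pbpk()
#' m$n
#' m$provenance
#' @export
fentanyl_pbpk <- function() {
  path <- system.file("extdata", "fentanyl_synthetic.json",
                      package = "autolump", mustWork = TRUE)
  read_model_json(path)
}

#' Physiological parameter table of the bundled 17-state model
#'
#' The [physiological_parameters()] table behind [fentanyl_pbpk()], for use
#' with [lumped_physiological_parameters()].
#'
#' @return a `physiological_parameters` data frame (17 rows).
#' @export
fentanyl_parameters <- function() {
  path <- system.file("extdata", "fentanyl_synthetic.json",
                      package = "autolump", mustWork = TRUE)
  physiological_parameters(jsonlite::fromJSON(path)$physiology)
}

#' Generate an exactly lumpable test system
#'
#' Builds a blood + tissues model in which each requested block consists of
#' identical-parameter tissue copies sharing the blood compartment as driver.
#' States with identical dynamics and identical input have identical
#' trajectories, so merging exactly those copies leaves the blood (output)
#' trajectory — and therefore the output AUC — unchanged: the returned
#' partition has ARD% = 0 up to floating-point error. Elimination is
#' first-order from blood, so the AUC is finite.
#'
#' @param block_sizes integer vector; block `b` contributes `block_sizes[b]`
#'   identical tissues. The true minimal lumped model has
#'   `length(block_sizes) + 1` states (blood plus one per block).
#' @param seed optional integer seed (parameters are drawn log-uniformly).
#' @return list with `model` (a [compartmental_model()], blood first and the
#'   output state) and `partition` (the true [lumping_partition()], blood
#'   constrained).
#' @export
exactly_lumpable_system <- function(block_sizes, seed = NULL) {
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) < 1 || any(block_sizes < 1))
    stop("`block_sizes` must be positive counts", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  b <- length(block_sizes)
  Qb <- 10^runif(b, -1, 0.5)
  Vb <- 10^runif(b, -0.5, 1)
  Kpb <- 10^runif(b, -0.5, 1)
  V_bl <- 10^runif(1, 0, 0.7)
  CL <- 10^runif(1, -1, 0.3)

  grp <- rep(seq_len(b), block_sizes)
  Q <- Qb[grp]; V <- Vb[grp]; Kp <- Kpb[grp]
  nt <- length(grp)
  n <- nt + 1L
  nm <- c("blood", paste0("T", grp, "_", sequence(block_sizes)))
  K <- matrix(0, n, n, dimnames = list(nm, nm))
  K[1, 1] <- -(sum(Q) + CL) / V_bl
  for (i in seq_len(nt)) {
    j <- i + 1L
    K[j, 1] <- Q[i] / V[i]
    K[1, j] <- Q[i] / (Kp[i] * V_bl)
    K[j, j] <- -Q[i] / (V[i] * Kp[i])
  }
  model <- compartmental_model(K, volumes = c(V_bl, V), output_state = 1L,
                               dose = list(state = 1L, amount = 100),
                               provenance = "synthetic-generator")
  partition <- lumping_partition(c(1L, grp + 1L), constrained = 1L)
  list(model = model, partition = partition)
}

#' Generate a random stable compartmental system
#'
#' A connected blood + tissues system with log-uniform flows, volumes and
#' partition coefficients (all tissues distinct) and first-order elimination
#' from blood, so every draw is mass balanced with a finite output AUC.
#' Deterministic under a fixed seed.
#'
#' @param n total number of states (blood plus `n - 1` tissues), `n >= 2`.
#' @param seed optional integer seed.
#' @return a [compartmental_model()] with blood (state 1) as output.
#' @export
random_compartmental_system <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  sys <- exactly_lumpable_system(rep(1L, n - 1L), seed = seed)
  sys$model
}
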