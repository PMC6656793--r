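#' Acceptance-criterion configuration
#'
#' The default criterion is `"ard-auc"`: the absolute relative difference (in
#' percent) between the output-state AUC of the lumped and original models,
#' with default tolerance 0.002%. A second, pluggable criterion
#' `"ss-trajectory"` (sum of squared differences of the output
#' concentration-time profile on a time grid) is provided for users who need
#' the whole profile rather than total exposure; it is not the default.
#'
#' @param kind `"ard-auc"` or `"ss-trajectory"`.
#' @param tolerance acceptance threshold: percent for `"ard-auc"`,
#'   concentration^2 x time-grid units for `"ss-trajectory"`. Must be > 0.
#' @param output_state optional index/name overriding the model's output.
#' @param times time grid for `"ss-trajectory"`; ignored by `"ard-auc"`.
#' @return object of class `criterion_config`.
#' @export
criterion_config <- function(kind = c("ard-auc", "ss-trajectory"),
                             tolerance = 0.002, output_state = NULL,
                             times = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("`tolerance` must be > 0", call. = FALSE)
  structure(list(kind = kind, tolerance = tolerance,
                 output_state = output_state, times = times),
            class = "criterion_config")
}

#' Absolute relative difference in percent
#'
#' `|auc_lumped - auc_original| / auc_original * 100`. The denominator is the
#' original model's AUC, the fixed reference.
#'
#' @param auc_original reference AUC, must be finite and positive.
#' @param auc_lumped AUC of the reduced model.
#' @return percent discrepancy (scalar, `Inf` if `auc_lumped` is not finite).
#' @export
ard_percent <- function(auc_original, auc_lumped) {
  if (!is.finite(auc_original) || auc_original <= 0)
    stop("reference AUC must be finite and positive", call. = FALSE)
  if (!is.finite(auc_lumped)) return(Inf)
  abs(auc_lumped - auc_original) / auc_original * 100
}

#' Evaluate a lumping partition against the acceptance criterion
#'
#' Builds the lumped system for `partition`, computes the criterion value
#' against the original model, and returns it (percent for the default
#' ARD-AUC criterion). The reference AUC (or reference trajectory) is
#' computed once per model and cached on the model object.
#'
#' If the lumped system has no finite AUC the returned value is `Inf`, with
#' a `diagnostic` attribute explaining why — an infinite discrepancy is never
#' acceptable but also never an error during a search.
#'
#' @param model a [compartmental_model()].
#' @param partition a [lumping_partition()].
#' @param config a [criterion_config()].
#' @return scalar criterion value (class-less numeric; `Inf` when the lumped
#'   system does not decay).
#' @examples
#' m <- compartmental_model(matrix(c(-1, 0.3, 0.5, -0.5), 2, 2), y0 = c(1, 0))
#' evaluate_partition(m, lumping_partition(c(1, 2)))  # identity: 0
#' @export
evaluate_partition <- function(model, partition, config = criterion_config()) {
  stopifnot(inherits(model, "compartmental_model"),
            inherits(partition, "lumping_partition"))
  out_state <- if (is.null(config$output_state)) model$output_state
               else resolve_state(config$output_state, model$state_names)
  if (config$kind == "ss-trajectory")
    return(evaluate_ss(model, partition, config, out_state))
  ref <- reference_auc(model, out_state)
  val <- ard_for_blocks(model$K, model$y0, out_state, partition$block_of, ref)
  if (!is.finite(val))
    attr(val, "diagnostic") <-
      "lumped system has no finite output AUC; partition not acceptable"
  val
}

# cached original-model output AUC
reference_auc <- function(model, out_state) {
  key <- paste0("auc_", out_state)
  val <- model$cache[[key]]
  if (is.null(val)) {
    val <- auc_to_infinity(model, out_state)
    if (!is.finite(val) || val <= 0)
      stop("original model has no finite positive output AUC", call. = FALSE)
    model$cache[[key]] <- val
  }
  val
}

# hot path shared by all search algorithms: ARD% for an integer block
# assignment, no partition object construction
ard_for_blocks <- function(K, y0, out_state, block_of, ref_auc) {
  m <- max(block_of)
  sizes <- tabulate(block_of, m)
  R <- rowsum(K, block_of, reorder = TRUE)
  K_hat <- t(rowsum(t(R), block_of, reorder = TRUE) / sizes)
  y0_hat <- rowsum(y0, block_of, reorder = TRUE)
  auc <- tryCatch(unname(-solve(K_hat, y0_hat)[block_of[out_state]]),
                  error = function(e) NA_real_)
  if (!is.finite(auc) || auc < 0) return(Inf)
  abs(auc - ref_auc) / ref_auc * 100
}

# sum-of-squares criterion on the output trajectory
evaluate_ss <- function(model, partition, config, out_state) {
  times <- config$times
  if (is.null(times)) {
    # default grid: 200 points over ~7 half-lives of the slowest decaying mode
    ev <- eigen(model$K, only.values = TRUE)$values
    rates <- abs(Re(ev)); rates <- rates[rates > 1e-12 * max(abs(model$K))]
    times <- seq(0, 5 / min(rates), length.out = 200L)
  }
  key <- paste0("ss_ref_", out_state, "_", length(times), "_",
                signif(max(times), 6))
  ref <- model$cache[[key]]
  if (is.null(ref)) {
    ref <- simulate_model(model, times)$trajectories[out_state, ]
    model$cache[[key]] <- ref
  }
  lm_ <- lump_model(model, partition)
  sim <- simulate_model(as_compartmental_model(lm_), times)
  cur <- sim$trajectories[lm_$output_block, ]
  sum((cur - ref)^2)
}
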