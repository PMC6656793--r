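#' Eigenvalue scree of a rate matrix
#'
#' Computes the eigenvalues of `K`, maps each to `log10(|lambda|)` (a zero
#' eigenvalue maps to `-Inf`), and ranks them in descending order. Ranked
#' log-magnitudes separate fast kinetic modes from slow ones; the number of
#' eigenvalues above a magnitude cutoff is used as an informative starting
#' number of lumped states for the random search ([incremental_search()]
#' with `method = "scree-nars"`).
#'
#' @param K square numeric matrix (or a [compartmental_model()], whose `K`
#'   is used).
#' @return object of class `scree_data`: list with `eigenvalues` (complex,
#'   unsorted), `ranked_log_abs` (descending), `n`.
#' @export
compute_scree <- function(K) {
  if (inherits(K, "compartmental_model")) K <- K$K
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("`K` must be square", call. = FALSE)
  ev <- eigen(K, only.values = TRUE)$values
  la <- ifelse(abs(ev) == 0, -Inf, log10(abs(ev)))
  structure(list(eigenvalues = ev,
                 ranked_log_abs = sort(la, decreasing = TRUE),
                 n = length(ev)),
            class = "scree_data")
}

#' @export
print.scree_data <- function(x, ...) {
  cat("<scree_data> n = ", x$n, "; ranked log10|eig|:\n", sep = "")
  print(signif(x$ranked_log_abs, 4))
  invisible(x)
}

#' Plot the scree of ranked eigenvalue magnitudes
#'
#' @param x a `scree_data` object.
#' @param cutoff horizontal reference line (default 0).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.scree_data <- function(x, cutoff = 0, ...) {
  y <- x$ranked_log_abs
  plot(seq_along(y), y, type = "b", xlab = "ranked state number",
       ylab = expression(log[10] * "|eig|"), ...)
  graphics::abline(h = cutoff, lty = 2)
  invisible(x)
}

#' Suggest an initial number of lumped states from the scree
#'
#' Two rules are available. `"cutoff"` (default): the number of ranked
#' `log10|eig|` values strictly above `cutoff` — eigenvalue magnitude 1 per
#' time unit at the default cutoff 0. `"slope"`: the rank just before the
#' largest consecutive drop in the ranked values (the elbow). Either way the
#' result is floored at 2, so the constrained output state plus at least one
#' lump always exist, and capped at `n`.
#'
#' @param scree a [compute_scree()] result.
#' @param cutoff threshold on `log10|eig|` for the `"cutoff"` rule.
#' @param rule `"cutoff"` or `"slope"`.
#' @return integer suggested number of lumped states.
#' @export
suggest_initial_states <- function(scree, cutoff = 0,
                                   rule = c("cutoff", "slope")) {
  stopifnot(inherits(scree, "scree_data"))
  rule <- match.arg(rule)
  r <- scree$ranked_log_abs
  k <- if (rule == "cutoff") {
    sum(r > cutoff)
  } else {
    fin <- r[is.finite(r)]
    if (length(fin) < 2) 1L else which.max(-diff(fin))
  }
  max(2L, min(as.integer(k), scree$n))
}

#' Write scree data to CSV
#'
#' Columns `rank,log10_abs_eig`.
#'
#' @param scree a `scree_data`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scree_csv <- function(scree, path) {
  write.csv(data.frame(rank = seq_len(scree$n),
                       log10_abs_eig = scree$ranked_log_abs),
            path, row.names = FALSE)
  invisible(path)
}
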