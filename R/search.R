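#' Search configuration
#'
#' @param method inner algorithm: `"enumeration"` (exhaustive over set
#'   partitions), `"nars"` (non-adaptive random search), `"scree-nars"`
#'   (NARS started at the scree-suggested state count), or `"sa"`
#'   (simulated annealing).
#' @param tolerance acceptance tolerance on ARD% (default 0.002).
#' @param constrained_states indices (or names, resolved against the model)
#'   of states kept unlumped; defaults to the model's output state.
#' @param nars_samples random samples per m-increment for NARS (default 1e4).
#' @param start_m number of lumped states to start from; `NULL` (default)
#'   means the fully lumped model, `1 + length(constrained_states)`. For
#'   `"scree-nars"`, `NULL` means the scree suggestion.
#' @param seed integer seed making stochastic methods reproducible.
#' @return object of class `search_config`.
#' @export
search_config <- function(method = c("enumeration", "nars", "scree-nars", "sa"),
                          tolerance = 0.002, constrained_states = NULL,
                          nars_samples = 1e4, start_m = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("`tolerance` must be > 0", call. = FALSE)
  if (!is.numeric(nars_samples) || nars_samples < 1)
    stop("`nars_samples` must be >= 1", call. = FALSE)
  structure(list(method = method, tolerance = tolerance,
                 constrained_states = constrained_states,
                 nars_samples = as.integer(nars_samples),
                 start_m = start_m, seed = seed),
            class = "search_config")
}

#' Simulated-annealing configuration
#'
#' Defaults: initial temperature `1e4`, multiplicative cooling factor
#' `0.999` per cycle (one Metropolis proposal per cycle), and a budget of
#' `2e4` proposals per m-level.
#'
#' @param initial_temperature starting temperature (dimensionless, same scale
#'   as the ARD% energy).
#' @param cooling_factor per-cycle multiplicative temperature decline,
#'   in (0, 1).
#' @param max_iterations proposal budget per m-level.
#' @return object of class `sa_config`.
#' @export
sa_config <- function(initial_temperature = 1e4, cooling_factor = 0.999,
                      max_iterations = 2e4) {
  if (!is.finite(initial_temperature) || initial_temperature <= 0)
    stop("`initial_temperature` must be > 0", call. = FALSE)
  if (!is.finite(cooling_factor) || cooling_factor <= 0 || cooling_factor >= 1)
    stop("`cooling_factor` must be in (0, 1)", call. = FALSE)
  if (max_iterations < 1) stop("`max_iterations` must be >= 1", call. = FALSE)
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 max_iterations = as.integer(max_iterations)),
            class = "sa_config")
}

#' Find a minimal lumped model by incremental search
#'
#' The outer loop of all four search methods. Starting from the fully lumped
#' model (every unconstrained state merged into a single block alongside the
#' constrained singletons), the inner algorithm looks for a partition at the
#' current number of lumped states `m` that meets the ARD% tolerance; if none
#' is found, `m` is incremented and the inner algorithm re-applied. The loop
#' terminates at the first `m` with an accepted partition, or with the
#' identity (unlumped) model at `m = n`, which always has ARD% = 0.
#'
#' @param model a [compartmental_model()].
#' @param config a [search_config()].
#' @param sa an [sa_config()]; used only by `method = "sa"`.
#' @return object of class `search_result`: list with `method`, `partition`,
#'   `m`, `ard_percent`, `evaluations`, `accepted`, `seed`, `trace`
#'   (simulated annealing only: data frame of iteration, temperature,
#'   current and best ARD%), `labeled_space` (the naive labelled-assignment
#'   count `m^n_free` at the final level, for reporting), and `start_m`.
#' @examples
#' sys <- exactly_lumpable_system(c(2, 2), seed = 1)
#' res <- incremental_search(sys$model,
#'                           search_config("enumeration", tolerance = 1e-4))
#' res$m
#' @export
incremental_search <- function(model, config = search_config(),
                               sa = sa_config()) {
  stopifnot(inherits(model, "compartmental_model"),
            inherits(config, "search_config"))
  n <- model$n
  constrained <- config$constrained_states
  constrained <- if (is.null(constrained)) model$output_state
                 else sort(unique(vapply(constrained, resolve_state,
                                         integer(1), model$state_names)))
  nc <- length(constrained)
  if (!is.null(config$seed)) set.seed(config$seed)

  start_m <- config$start_m
  if (is.null(start_m)) {
    start_m <- if (config$method == "scree-nars")
      suggest_initial_states(compute_scree(model$K)) else nc + 1L
  }
  start_m <- max(start_m, nc + 1L)
  start_m <- min(start_m, n)

  out_state <- model$output_state
  ref <- reference_auc(model, out_state)
  evaluations <- 0L
  trace <- NULL

  for (m in start_m:n) {
    if (m == n) {
      part <- lumping_partition(seq_len(n), constrained = constrained)
      return(new_search_result(config, part, ard = 0, evaluations,
                               accepted = TRUE, trace, n, nc, start_m))
    }
    inner <- switch(config$method,
      "enumeration" = enum_level(model, m, constrained, config$tolerance,
                                 ref, stop_at_first = TRUE),
      "nars" = ,
      "scree-nars" = nars_level(model, m, constrained, config$nars_samples,
                                config$tolerance, ref),
      "sa" = sa_level(model, m, constrained, sa, config$tolerance, ref))
    evaluations <- evaluations + inner$evaluations
    if (config$method == "sa") trace <- inner$trace
    if (!is.null(inner$accepted_blocks)) {
      part <- lumping_partition(inner$accepted_blocks,
                                constrained = constrained)
      return(new_search_result(config, part, inner$accepted_ard, evaluations,
                               accepted = TRUE, trace, n, nc, start_m))
    }
  }
}

new_search_result <- function(config, partition, ard, evaluations, accepted,
                              trace, n, nc, start_m) {
  structure(list(method = config$method, partition = partition,
                 m = partition$m, ard_percent = as.numeric(ard),
                 evaluations = evaluations, accepted = accepted,
                 tolerance = config$tolerance, seed = config$seed,
                 trace = trace, start_m = start_m,
                 labeled_space = partition$m^(n - nc)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> method = ", x$method, "\n",
      "  lumped states m = ", x$m, ", ARD% = ", format(x$ard_percent),
      " (tolerance ", x$tolerance, "%)\n",
      "  accepted = ", x$accepted, ", evaluations = ", x$evaluations,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed) else "", "\n",
      sep = "")
  print(x$partition)
  invisible(x)
}

#' Exhaustive search at a fixed number of lumped states
#'
#' Evaluates every constrained set partition with `m` blocks and returns the
#' global minimum-ARD% partition (ties broken by iteration order: first
#' encountered wins) together with the first partition in lexicographic
#' restricted-growth order that meets the tolerance, if any. The first
#' accepted partition is order-dependent; the minimum is not.
#'
#' @param model a [compartmental_model()].
#' @param m number of lumped states.
#' @param config a [search_config()] (tolerance and constrained states are
#'   used).
#' @param stop_at_first stop as soon as a partition meets the tolerance
#'   (the behaviour the incremental outer loop uses).
#' @return list with `best_partition`, `min_ard`, `first_accepted` (a
#'   `lumping_partition` or `NULL`), `first_accepted_ard`, `evaluations`,
#'   `space_size`.
#' @export
full_enumeration_at_m <- function(model, m, config = search_config(),
                                  stop_at_first = FALSE) {
  constrained <- config$constrained_states
  constrained <- if (is.null(constrained)) model$output_state
                 else sort(unique(vapply(constrained, resolve_state,
                                         integer(1), model$state_names)))
  ref <- reference_auc(model, model$output_state)
  lev <- enum_level(model, m, constrained, config$tolerance, ref,
                    stop_at_first = stop_at_first)
  list(best_partition = lumping_partition(lev$best_blocks,
                                          constrained = constrained),
       min_ard = lev$best_ard,
       first_accepted = if (is.null(lev$accepted_blocks)) NULL
                        else lumping_partition(lev$accepted_blocks,
                                               constrained = constrained),
       first_accepted_ard = lev$accepted_ard,
       evaluations = lev$evaluations,
       space_size = lev$space_size)
}

enum_level <- function(model, m, constrained, tolerance, ref,
                       stop_at_first = FALSE) {
  it <- partition_iterator(model$n, m, constrained)
  K <- model$K; y0 <- model$y0; out <- model$output_state
  best_ard <- Inf; best_blocks <- NULL
  acc_blocks <- NULL; acc_ard <- NA_real_
  evaluations <- 0L
  repeat {
    g <- it$next_partition()
    if (is.null(g)) break
    evaluations <- evaluations + 1L
    ard <- ard_for_blocks(K, y0, out, g, ref)
    if (ard < best_ard) { best_ard <- ard; best_blocks <- g }
    if (is.null(acc_blocks) && ard <= tolerance) {
      acc_blocks <- g; acc_ard <- ard
      if (stop_at_first) break
    }
  }
  list(best_blocks = best_blocks, best_ard = best_ard,
       accepted_blocks = acc_blocks, accepted_ard = acc_ard,
       evaluations = evaluations, space_size = it$size)
}

#' Non-adaptive random search at a fixed number of lumped states
#'
#' Draws `n_samples` uniformly random legal partitions with `m` blocks,
#' evaluates each, and returns the best found; short-circuits on the first
#' partition meeting the tolerance.
#'
#' @inheritParams full_enumeration_at_m
#' @param n_samples number of random draws.
#' @return list with `best_partition`, `best_ard`, `accepted` (logical),
#'   `evaluations`.
#' @export
nars_at_m <- function(model, m, n_samples, config = search_config()) {
  constrained <- config$constrained_states
  constrained <- if (is.null(constrained)) model$output_state
                 else sort(unique(vapply(constrained, resolve_state,
                                         integer(1), model$state_names)))
  if (!is.null(config$seed)) set.seed(config$seed)
  ref <- reference_auc(model, model$output_state)
  lev <- nars_level(model, m, constrained, n_samples, config$tolerance, ref)
  list(best_partition = lumping_partition(lev$best_blocks,
                                          constrained = constrained),
       best_ard = lev$best_ard,
       accepted = !is.null(lev$accepted_blocks),
       evaluations = lev$evaluations)
}

nars_level <- function(model, m, constrained, n_samples, tolerance, ref) {
  n <- model$n
  free <- setdiff(seq_len(n), constrained)
  k <- m - length(constrained)
  K <- model$K; y0 <- model$y0; out <- model$output_state
  best_ard <- Inf; best_blocks <- NULL
  acc_blocks <- NULL; acc_ard <- NA_real_
  evaluations <- 0L
  g <- integer(n)
  g[constrained] <- seq_along(constrained)
  nc <- length(constrained)
  # a level with a single legal partition needs a single evaluation
  if (k == 1L || k == length(free)) n_samples <- 1L
  for (s in seq_len(n_samples)) {
    repeat {
      a <- sample.int(k, length(free), replace = TRUE)
      if (k == 1L || length(unique(a)) == k) break
    }
    g[free] <- a + nc
    evaluations <- evaluations + 1L
    ard <- ard_for_blocks(K, y0, out, g, ref)
    if (ard < best_ard) { best_ard <- ard; best_blocks <- g }
    if (ard <= tolerance) { acc_blocks <- g; acc_ard <- ard; break }
  }
  list(best_blocks = best_blocks, best_ard = best_ard,
       accepted_blocks = acc_blocks, accepted_ard = acc_ard,
       evaluations = evaluations)
}

#' Metropolis acceptance rule
#'
#' Accept an uphill move of size `delta_ard` at temperature `temperature`
#' with probability `exp(-delta_ard / temperature)`; downhill or flat moves
#' (`delta_ard <= 0`) are always accepted.
#'
#' @param delta_ard change in the energy (ARD%) of the proposed solution.
#' @param temperature current annealing temperature, must be > 0.
#' @return logical: accept the proposal?
#' @export
metropolis_accept <- function(delta_ard, temperature) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be > 0", call. = FALSE)
  if (delta_ard <= 0) return(TRUE)
  if (!is.finite(delta_ard)) return(FALSE)
  runif(1) < exp(-delta_ard / temperature)
}

#' Simulated annealing at a fixed number of lumped states
#'
#' Starts from a uniformly random legal partition with `m` blocks; each cycle
#' proposes moving one free state to a different block (proposals that would
#' empty a block are never generated), accepts by the Metropolis rule on the
#' change in ARD%, and multiplies the temperature by the cooling factor. Runs
#' until the tolerance is met or the iteration budget is exhausted, and
#' returns the best partition ever visited plus the per-iteration trace.
#'
#' @inheritParams full_enumeration_at_m
#' @param sa an [sa_config()].
#' @return list with `best_partition`, `best_ard`, `accepted`, `evaluations`,
#'   `trace` (data frame: `iteration`, `temperature`, `current_ard`,
#'   `best_ard`).
#' @export
sa_at_m <- function(model, m, sa = sa_config(), config = search_config()) {
  constrained <- config$constrained_states
  constrained <- if (is.null(constrained)) model$output_state
                 else sort(unique(vapply(constrained, resolve_state,
                                         integer(1), model$state_names)))
  if (!is.null(config$seed)) set.seed(config$seed)
  ref <- reference_auc(model, model$output_state)
  lev <- sa_level(model, m, constrained, sa, config$tolerance, ref)
  blocks <- if (is.null(lev$accepted_blocks)) lev$best_blocks
            else lev$accepted_blocks
  list(best_partition = lumping_partition(blocks, constrained = constrained),
       best_ard = lev$best_ard,
       accepted = !is.null(lev$accepted_blocks),
       evaluations = lev$evaluations, trace = lev$trace)
}

sa_level <- function(model, m, constrained, sa, tolerance, ref) {
  n <- model$n
  free <- setdiff(seq_len(n), constrained)
  K <- model$K; y0 <- model$y0; out <- model$output_state

  cur <- sample_random_partition(n, m, constrained)$block_of
  forbidden <- cur[constrained]  # constrained singleton blocks never gain members
  cur_ard <- ard_for_blocks(K, y0, out, cur, ref)
  best <- cur; best_ard <- cur_ard
  evaluations <- 1L
  iters <- sa$max_iterations
  tr_temp <- numeric(iters); tr_cur <- numeric(iters); tr_best <- numeric(iters)
  temp <- sa$initial_temperature
  it <- 0L
  acc_blocks <- if (best_ard <= tolerance) best else NULL

  while (is.null(acc_blocks) && it < iters) {
    it <- it + 1L
    cand <- propose_neighbour(cur, free, m, forbidden)
    if (is.null(cand)) break  # all free blocks are singletons: nowhere to move
    cand_ard <- ard_for_blocks(K, y0, out, cand, ref)
    evaluations <- evaluations + 1L
    delta <- cand_ard - cur_ard
    if (is.nan(delta)) delta <- 0  # both infinite: indifferent, keep moving
    if (metropolis_accept(delta, temp)) {
      cur <- cand; cur_ard <- cand_ard
    }
    if (cand_ard < best_ard) { best <- cand; best_ard <- cand_ard }
    tr_temp[it] <- temp; tr_cur[it] <- cur_ard; tr_best[it] <- best_ard
    if (best_ard <= tolerance) acc_blocks <- best
    temp <- temp * sa$cooling_factor
  }
  trace <- data.frame(iteration = seq_len(it),
                      temperature = tr_temp[seq_len(it)],
                      current_ard = tr_cur[seq_len(it)],
                      best_ard = tr_best[seq_len(it)])
  list(best_blocks = best, best_ard = best_ard,
       accepted_blocks = acc_blocks,
       accepted_ard = if (is.null(acc_blocks)) NA_real_ else best_ard,
       evaluations = evaluations, trace = trace)
}
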