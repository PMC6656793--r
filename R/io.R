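#' Read a compartmental model from JSON
#'
#' Two schemas are accepted. A rate-matrix model:
#' `{"states": [...], "rate_matrix": [[...]], "volumes": [...],
#'   "output_state": "...", "dose": {"state": "...", "amount": x}}`
#' or a physiological model:
#' `{"physiology": [{"name", "type", "Q", "V", "Kp", ...}],
#'   "output_state": "...", "dose": {...}}`,
#' which is passed through [physiological_parameters()] and
#' [build_rate_matrix()]. An optional top-level `"provenance"` string is
#' carried onto the model.
#'
#' @param path JSON file path.
#' @return a [compartmental_model()].
#' @export
read_model_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  dose <- if (!is.null(x$dose)) list(state = x$dose$state,
                                     amount = x$dose$amount)
  if (!is.null(x$physiology)) {
    params <- physiological_parameters(x$physiology)
    out <- if (is.null(x$output_state)) "arterial" else x$output_state
    build_rate_matrix(params, output_state = out, dose = dose,
                      provenance = x$provenance)
  } else {
    if (is.null(x$rate_matrix))
      stop("model JSON needs either 'physiology' or 'rate_matrix'",
           call. = FALSE)
    compartmental_model(
      K = as.matrix(x$rate_matrix),
      state_names = x$states, volumes = x$volumes,
      output_state = if (is.null(x$output_state)) 1L else x$output_state,
      y0 = x$y0, dose = dose, provenance = x$provenance,
      check_balance = !isFALSE(x$check_balance))
  }
}

#' Write a compartmental model to JSON (rate-matrix schema)
#'
#' @param model a [compartmental_model()] or [lumped_model][lump_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  model <- as_compartmental_model(model)
  x <- list(states = model$state_names,
            rate_matrix = unname(model$K),
            volumes = unname(model$volumes),
            output_state = model$state_names[model$output_state],
            y0 = unname(model$y0),
            provenance = model$provenance,
            check_balance = model$balance_checked)
  if (!is.null(model$dose))
    x$dose <- list(state = model$state_names[model$dose$state],
                   amount = model$dose$amount)
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a lumping partition as CSV
#'
#' Columns `state,block,constrained`; `state` holds names when available.
#'
#' @param partition a [lumping_partition()].
#' @param path file path.
#' @param state_names optional state names for the `state` column.
#' @return `path` (write) or a [lumping_partition()] (read).
#' @export
write_partition_csv <- function(partition, path, state_names = NULL) {
  stopifnot(inherits(partition, "lumping_partition"))
  st <- if (is.null(state_names)) seq_len(partition$n) else state_names
  write.csv(data.frame(state = st, block = partition$block_of,
                       constrained = seq_len(partition$n) %in%
                         partition$constrained),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  x <- read.csv(path)
  constrained <- if (!is.null(x$constrained)) which(as.logical(x$constrained))
                 else integer()
  lumping_partition(x$block, constrained = constrained)
}

#' Write an SA search trace to CSV
#'
#' Columns `iteration,temperature,current_ard,best_ard`.
#'
#' @param trace trace data frame from a [search_result][incremental_search()]
#'   or [sa_at_m()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  write.csv(trace[, c("iteration", "temperature", "current_ard", "best_ard")],
            path, row.names = FALSE)
  invisible(path)
}

#' Serialise a search result as a run report
#'
#' The report is a JSON document carrying everything needed to audit and
#' reproduce a search: method, configuration echo, final number of lumped
#' states, ARD%, block composition with state names, evaluation count,
#' wall time, and seed. [read_search_report()] restores it losslessly (the
#' trace is stored separately via [write_trace_csv()]).
#'
#' @param result a [search_result][incremental_search()].
#' @param path output JSON path.
#' @param model the searched model (for state names and digest); optional.
#' @param wall_time elapsed seconds to record; optional.
#' @return `path`, invisibly.
#' @export
write_search_report <- function(result, path, model = NULL, wall_time = NULL) {
  stopifnot(inherits(result, "search_result"))
  blocks <- lapply(result$partition$blocks, function(ix) {
    if (is.null(model)) ix else model$state_names[ix]
  })
  rep_ <- list(method = result$method,
               tolerance = result$tolerance,
               seed = result$seed,
               start_m = result$start_m,
               m = result$m,
               ard_percent = result$ard_percent,
               accepted = result$accepted,
               evaluations = result$evaluations,
               labeled_space = result$labeled_space,
               block_of = result$partition$block_of,
               constrained = result$partition$constrained,
               blocks = blocks,
               wall_time_s = wall_time,
               model_digest = if (!is.null(model)) model_digest(model))
  jsonlite::write_json(rep_[!vapply(rep_, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_search_report
#' @export
read_search_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$block_of <- as.integer(x$block_of)
  x$constrained <- as.integer(x$constrained)
  for (f in c("ard_percent", "tolerance", "labeled_space", "wall_time_s"))
    if (!is.null(x[[f]])) x[[f]] <- as.numeric(x[[f]])
  for (f in c("m", "start_m", "evaluations", "seed"))
    if (!is.null(x[[f]])) x[[f]] <- as.integer(x[[f]])
  x
}

# md5 digest of the model's rate matrix and initial condition
model_digest <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(list(K = unname(model$K), y0 = unname(model$y0)),
                       tf, digits = NA)
  unname(tools::md5sum(tf))
}
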