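#' Construct a linear compartmental model
#'
#' Represents the linear system `dy/dt = K y`, where `y` is a vector of state
#' concentrations and `K` is the matrix of micro rate constants (per unit
#' time). This is the object every other function in the package operates on:
#' it can be simulated in closed form with [simulate_model()], reduced with
#' [lump_model()], and searched over with [incremental_search()].
#'
#' When `volumes` are supplied the model is validated for mass balance: the
#' amount-basis matrix `diag(V) K diag(V)^-1` must have every column sum
#' `<= 0` (strictly negative only in columns with elimination). Set
#' `check_balance = FALSE` to skip this check, e.g. for reduced systems whose
#' rate matrix is not exactly mass balanced.
#'
#' A bolus dose may be given instead of `y0`: the dosed amount is converted to
#' a concentration through the dosed state's volume.
#'
#' @param K square numeric matrix of micro rate constants (per time).
#' @param state_names character vector of state identifiers; defaults to the
#'   row names of `K` or `S1..Sn`.
#' @param volumes optional positive per-state volumes (same order as states).
#' @param output_state index or name of the observation state (default first).
#' @param y0 nonnegative initial concentration vector; exactly one of `y0`
#'   and `dose` must be given.
#' @param dose list with elements `state` (index or name) and `amount`
#'   (mass units); requires `volumes`.
#' @param provenance optional character tag recording where the numeric
#'   parameters came from (e.g. `"synthetic-placeholder"`).
#' @param check_balance logical; validate amount-basis column sums when
#'   volumes are present (default `TRUE`).
#'
#' @return An object of class `compartmental_model`: a list with elements
#'   `state_names`, `K`, `volumes`, `output_state`, `y0`, `dose`, `n`.
#' @examples
#' m <- compartmental_model(K = matrix(c(-0.5, 0.5, 0.2, -0.2), 2, 2),
#'                          state_names = c("blood", "tissue"),
#'                          y0 = c(1, 0))
#' m$n
#' @export
compartmental_model <- function(K, state_names = NULL, volumes = NULL,
                                output_state = 1L, y0 = NULL, dose = NULL,
                                provenance = NULL, check_balance = TRUE) {
  K <- as.matrix(K)
  if (!is.numeric(K) || nrow(K) != ncol(K))
    stop("`K` must be a square numeric matrix", call. = FALSE)
  n <- nrow(K)
  if (n < 2L) stop("a compartmental model needs at least 2 states", call. = FALSE)
  if (!all(is.finite(K))) stop("`K` contains non-finite entries", call. = FALSE)

  if (is.null(state_names)) state_names <- rownames(K)
  if (is.null(state_names)) state_names <- paste0("S", seq_len(n))
  if (length(state_names) != n || anyDuplicated(state_names))
    stop("`state_names` must be ", n, " unique identifiers", call. = FALSE)
  dimnames(K) <- list(state_names, state_names)

  if (!is.null(volumes)) {
    if (length(volumes) != n || !all(is.finite(volumes)) || any(volumes <= 0))
      stop("`volumes` must be ", n, " finite positive values", call. = FALSE)
    volumes <- as.numeric(volumes)
    names(volumes) <- state_names
  }

  output_state <- resolve_state(output_state, state_names)

  if (is.null(y0) && is.null(dose))
    stop("supply an initial condition `y0` or a bolus `dose`", call. = FALSE)
  if (!is.null(dose)) {
    if (!is.list(dose) || is.null(dose$state) || is.null(dose$amount))
      stop("`dose` must be list(state=, amount=)", call. = FALSE)
    if (is.null(volumes))
      stop("a bolus `dose` needs `volumes` to convert mass to concentration",
           call. = FALSE)
    ds <- resolve_state(dose$state, state_names)
    if (!is.finite(dose$amount) || dose$amount <= 0)
      stop("dose amount must be a positive number", call. = FALSE)
    if (is.null(y0)) {
      y0 <- numeric(n)
      y0[ds] <- dose$amount / volumes[ds]
    }
    dose <- list(state = ds, amount = as.numeric(dose$amount))
  }
  y0 <- as.numeric(y0)
  if (length(y0) != n || !all(is.finite(y0)) || any(y0 < 0) || all(y0 == 0))
    stop("`y0` must be nonnegative with at least one positive entry",
         call. = FALSE)
  names(y0) <- state_names

  if (!is.null(volumes) && check_balance) {
    cs <- colSums(amount_basis_matrix(K, volumes))
    tol <- 1e-8 * max(abs(K)) * max(volumes) / min(volumes)
    if (any(cs > tol))
      stop("mass balance violated: amount-basis column sum > 0 for state(s) ",
           paste(state_names[cs > tol], collapse = ", "), call. = FALSE)
  }

  structure(
    list(state_names = state_names, K = K, volumes = volumes,
         output_state = output_state, y0 = y0, dose = dose, n = n,
         provenance = provenance,
         balance_checked = isTRUE(check_balance) && !is.null(volumes),
         cache = new.env(parent = emptyenv())),
    class = "compartmental_model")
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat("<compartmental_model> ", x$n, " states, output = ",
      x$state_names[x$output_state], "\n", sep = "")
  if (!is.null(x$dose))
    cat("  bolus dose ", x$dose$amount, " into ",
        x$state_names[x$dose$state], "\n", sep = "")
  elim <- eliminating_states(x)
  cat("  eliminating state(s): ",
      if (length(elim)) paste(x$state_names[elim], collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

# map a state name or index to a validated integer index
resolve_state <- function(state, state_names) {
  n <- length(state_names)
  if (is.character(state)) {
    i <- match(state, state_names)
    if (is.na(i)) stop("unknown state '", state, "'", call. = FALSE)
    return(i)
  }
  i <- as.integer(state)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop("state index out of range 1..", n, call. = FALSE)
  i
}

# K in the amount basis: diag(V) K diag(V)^-1
amount_basis_matrix <- function(K, volumes) {
  if (is.null(volumes)) return(K)
  K * outer(volumes, 1 / volumes)
}

#' States with net elimination
#'
#' Indices of states whose amount-basis column sum is strictly negative,
#' i.e. states from which mass leaves the system.
#'
#' @param model a [compartmental_model()].
#' @param tol absolute tolerance on the column sum.
#' @return integer vector of state indices.
#' @export
eliminating_states <- function(model, tol = NULL) {
  A <- amount_basis_matrix(model$K, model$volumes)
  if (is.null(tol)) tol <- 1e-10 * max(abs(A))
  which(colSums(A) < -tol)
}
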