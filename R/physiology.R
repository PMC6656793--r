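#' Physiological parameter table for a perfusion-limited PBPK model
#'
#' Validates and normalises a per-state table of physiological parameters from
#' which [build_rate_matrix()] constructs the micro-rate-constant matrix.
#'
#' One row per state, in the state order the resulting model will use.
#' Columns:
#' \describe{
#'   \item{name}{unique state identifier.}
#'   \item{type}{one of `"arterial"`, `"venous"`, `"lung"`, `"tissue"`,
#'     `"sub"` (an extra first-order sub-compartment attached to a tissue).}
#'   \item{Q}{blood flow (volume/time). Required for tissues; for the lung it
#'     is the cardiac output. Ignored for blood and sub-compartments.}
#'   \item{V}{volume (volume units), required and positive for every state.}
#'   \item{Kp}{tissue:blood partition coefficient, required positive for lung
#'     and tissues.}
#'   \item{CL}{optional intrinsic clearance (volume/time) acting on the
#'     state's emergent (tissue/Kp) concentration; default 0.}
#'   \item{drains_to}{`"venous"` (default) or `"liver"` for portal tissues
#'     (spleen, gut) whose venous outflow passes through the liver.}
#'   \item{parent}{for `type == "sub"`, the name of the tissue the
#'     sub-compartment exchanges with.}
#'   \item{k_in, k_out}{for `type == "sub"`, nonnegative first-order exchange
#'     rates (per time) in the amount basis:
#'     `dA_sub/dt = k_in A_parent - k_out A_sub`.}
#' }
#'
#' The sum of tissue blood flows (counting the liver's own `Q` as hepatic
#' arterial flow) must equal the cardiac output (the lung `Q`) within
#' `flow_tolerance` (relative).
#'
#' @param table data frame as described above.
#' @param flow_tolerance relative tolerance for the flow balance check.
#' @return the normalised table, class `physiological_parameters`.
#' @export
physiological_parameters <- function(table, flow_tolerance = 1e-6) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  req <- c("name", "type", "V")
  if (!all(req %in% names(table)))
    stop("parameter table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  for (col in c("Q", "Kp", "CL", "k_in", "k_out"))
    if (is.null(table[[col]])) table[[col]] <- NA_real_
  if (is.null(table$drains_to)) table$drains_to <- NA_character_
  if (is.null(table$parent)) table$parent <- NA_character_
  table$CL[is.na(table$CL)] <- 0

  if (anyDuplicated(table$name))
    stop("duplicated state names in parameter table", call. = FALSE)
  ok_types <- c("arterial", "venous", "lung", "tissue", "sub")
  if (!all(table$type %in% ok_types))
    stop("`type` must be one of: ", paste(ok_types, collapse = ", "),
         call. = FALSE)
  for (tp in c("arterial", "venous", "lung"))
    if (sum(table$type == tp) != 1L)
      stop("exactly one state of type '", tp, "' is required", call. = FALSE)

  if (any(!is.finite(table$V) | table$V <= 0))
    stop("all volumes V must be positive", call. = FALSE)
  tis <- table$type == "tissue"
  lng <- table$type == "lung"
  if (any(!is.finite(table$Q[tis | lng]) | table$Q[tis | lng] <= 0))
    stop("blood flow Q must be positive for lung and every tissue",
         call. = FALSE)
  if (any(!is.finite(table$Kp[tis | lng]) | table$Kp[tis | lng] <= 0))
    stop("partition coefficient Kp must be positive for lung and every tissue",
         call. = FALSE)
  if (any(table$CL < 0)) stop("clearance CL must be nonnegative", call. = FALSE)

  table$drains_to[tis & is.na(table$drains_to)] <- "venous"
  bad <- tis & !table$drains_to %in% c("venous", "liver")
  if (any(bad))
    stop("drains_to must be 'venous' or 'liver' (state ",
         table$name[bad][1], ")", call. = FALSE)

  sub <- table$type == "sub"
  if (any(sub)) {
    if (any(is.na(table$parent[sub])))
      stop("sub-compartments need a `parent` tissue", call. = FALSE)
    orphan <- !table$parent[sub] %in% table$name[tis]
    if (any(orphan))
      stop("orphan sub-compartment '", table$name[sub][orphan][1],
           "': parent '", table$parent[sub][orphan][1],
           "' is not a tissue in the table", call. = FALSE)
    kk <- c(table$k_in[sub], table$k_out[sub])
    if (any(!is.finite(kk) | kk < 0))
      stop("sub-compartment exchange rates k_in/k_out must be >= 0",
           call. = FALSE)
  }

  co <- table$Q[lng]
  qsum <- sum(table$Q[tis])
  if (abs(qsum - co) > flow_tolerance * co)
    stop("sum of tissue flows (", signif(qsum, 8),
         ") does not match cardiac output (", signif(co, 8), ")",
         call. = FALSE)

  class(table) <- c("physiological_parameters", "data.frame")
  table
}

#' Build the micro-rate-constant matrix from physiological parameters
#'
#' Encodes perfusion-limited (flow-limited) kinetics in the concentration
#' basis. Each tissue `i` gains from arterial blood at rate `Q_i/V_i` and
#' returns at `Q_i/(V_i Kp_i)`; portal tissues drain via the liver; the lung
#' sits between venous and arterial blood and carries the full cardiac
#' output; intrinsic clearance appears as an extra first-order loss on the
#' emergent concentration of the eliminating state; sub-compartments exchange
#' first-order with their parent tissue in the amount basis.
#'
#' @param params a [physiological_parameters()] table (or a plain data frame,
#'   which is validated first).
#' @param output_state name of the observation state (default `"arterial"`).
#' @param dose list(state=, amount=) bolus dose; default 1 unit into the
#'   output state.
#' @param provenance optional provenance tag carried into the model.
#' @return a [compartmental_model()] whose state order is the row order of
#'   `params`.
#' @examples
#' tab <- data.frame(
#'   name = c("arterial", "venous", "lung", "muscle"),
#'   type = c("arterial", "venous", "lung", "tissue"),
#'   Q = c(NA, NA, 5, 5), V = c(1.5, 3.5, 0.5, 30), Kp = c(NA, NA, 1, 3))
#' m <- build_rate_matrix(tab, dose = list(state = "arterial", amount = 100))
#' round(m$K, 3)
#' @export
build_rate_matrix <- function(params, output_state = "arterial",
                              dose = list(state = "arterial", amount = 1),
                              provenance = NULL) {
  if (!inherits(params, "physiological_parameters"))
    params <- physiological_parameters(params)
  n <- nrow(params)
  nm <- params$name
  K <- matrix(0, n, n, dimnames = list(nm, nm))
  idx <- function(x) match(x, nm)

  i_art <- which(params$type == "arterial")
  i_ven <- which(params$type == "venous")
  i_lng <- which(params$type == "lung")
  V <- params$V
  co <- params$Q[i_lng]

  # lung: venous -> lung -> arterial, full cardiac output
  K[i_lng, i_ven] <- K[i_lng, i_ven] + co / V[i_lng]
  K[i_ven, i_ven] <- K[i_ven, i_ven] - co / V[i_ven]
  k_lu_out <- co / (V[i_lng] * params$Kp[i_lng])
  K[i_art, i_lng] <- K[i_art, i_lng] + k_lu_out * V[i_lng] / V[i_art]
  K[i_lng, i_lng] <- K[i_lng, i_lng] - k_lu_out
  K[i_art, i_art] <- K[i_art, i_art] - co / V[i_art]

  # portal inflow raises the receiving tissue's total outflow (Q_ha + Q_portal)
  portal_in <- numeric(n)
  for (i in which(params$type == "tissue" & params$drains_to == "liver")) {
    dest <- idx("liver")
    if (is.na(dest))
      stop("tissue '", nm[i], "' drains to liver but no state named 'liver'",
           call. = FALSE)
    portal_in[dest] <- portal_in[dest] + params$Q[i]
  }

  for (i in which(params$type == "tissue")) {
    Q <- params$Q[i]; Kp <- params$Kp[i]
    # arterial inflow
    K[i, i_art] <- K[i, i_art] + Q / V[i]
    # venous return, possibly via liver (portal flow)
    dest <- if (params$drains_to[i] == "liver") idx("liver") else i_ven
    k_out <- (Q + portal_in[i]) / (V[i] * Kp)
    K[dest, i] <- K[dest, i] + k_out * V[i] / V[dest]
    K[i, i] <- K[i, i] - k_out
    # elimination: clearance on the emergent concentration C_i/Kp
    if (params$CL[i] > 0)
      K[i, i] <- K[i, i] - params$CL[i] / (V[i] * Kp)
  }

  for (i in which(params$type == "sub")) {
    p <- idx(params$parent[i])
    kin <- params$k_in[i]; kout <- params$k_out[i]
    # amount-basis exchange dA_i/dt = kin*A_p - kout*A_i, in concentrations
    K[i, p] <- K[i, p] + kin * V[p] / V[i]
    K[p, p] <- K[p, p] - kin
    K[p, i] <- K[p, i] + kout * V[i] / V[p]
    K[i, i] <- K[i, i] - kout
  }

  compartmental_model(K, state_names = nm, volumes = V,
                      output_state = output_state, dose = dose,
                      provenance = provenance)
}
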