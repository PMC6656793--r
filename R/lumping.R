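#' Define a proper-lumping partition
#'
#' A proper lumping assigns each original state to exactly one lumped block,
#' which is exactly a set partition of the states. The partition, not the 0/1
#' lumping matrix, is the internal representation: block labels are
#' canonicalised by order of first appearance (a restricted growth string),
#' so two equal partitions always compare equal and the label symmetry of the
#' matrix representation disappears from the search space. The matrix is
#' materialised on demand by [make_lumping_matrix()].
#'
#' @param block_of vector of length n assigning each state a block label
#'   (any type; labels are canonicalised to `1..m`).
#' @param constrained integer indices of states that must remain unlumped
#'   (each alone in its block), e.g. the observation state.
#' @return object of class `lumping_partition`: list with `block_of`
#'   (canonical integer labels), `m`, `n`, `constrained`, `blocks` (list of
#'   member index vectors).
#' @examples
#' p <- lumping_partition(c(1, 1, 2))   # merge states 1 and 2 of a 3-state model
#' make_lumping_matrix(p)
#' @export
lumping_partition <- function(block_of, constrained = integer()) {
  n <- length(block_of)
  if (n < 1L || anyNA(block_of))
    stop("`block_of` must be a complete assignment of states to blocks",
         call. = FALSE)
  lab <- canonical_labels(block_of)
  m <- max(lab)
  constrained <- sort(unique(as.integer(constrained)))
  if (length(constrained) && (min(constrained) < 1L || max(constrained) > n))
    stop("constrained state index out of range", call. = FALSE)
  sizes <- tabulate(lab, m)
  for (s in constrained)
    if (sizes[lab[s]] != 1L)
      stop("constrained state ", s, " must be alone in its block",
           call. = FALSE)
  blocks <- split(seq_len(n), lab)
  names(blocks) <- NULL
  structure(list(block_of = lab, m = m, n = n, constrained = constrained,
                 blocks = blocks),
            class = "lumping_partition")
}

# relabel blocks 1..m in order of first appearance (restricted growth string)
canonical_labels <- function(block_of) {
  f <- factor(block_of, levels = unique(block_of))
  as.integer(f)
}

#' @export
print.lumping_partition <- function(x, ...) {
  cat("<lumping_partition> n = ", x$n, ", m = ", x$m, " blocks\n", sep = "")
  for (b in seq_len(x$m))
    cat("  block ", b, ": {", paste(x$blocks[[b]], collapse = ","), "}\n",
        sep = "")
  invisible(x)
}

#' @export
format.lumping_partition <- function(x, ...) {
  paste(x$block_of, collapse = "-")
}

#' Materialise the 0/1 lumping matrix M
#'
#' Row `b` of the m x n matrix has ones exactly at the member states of block
#' `b`; every column sums to 1 (each state belongs to one block). The
#' identity partition yields the n x n identity matrix.
#'
#' @param partition a [lumping_partition()].
#' @return m x n matrix of 0s and 1s.
#' @export
make_lumping_matrix <- function(partition) {
  stopifnot(inherits(partition, "lumping_partition"))
  M <- matrix(0, partition$m, partition$n)
  M[cbind(partition$block_of, seq_len(partition$n))] <- 1
  M
}

#' Moore-Penrose pseudo-inverse of a lumping matrix
#'
#' For a legal 0/1 lumping matrix, `M M^T` is the diagonal matrix of block
#' sizes, so `M+ = M^T (M M^T)^-1` has column `b` equal to `1/|block b|` at
#' the members of block `b`: lumping sums member concentrations, the
#' pseudo-inverse distributes a lumped concentration back as the block
#' average. Satisfies all four Penrose conditions.
#'
#' @param M a legal lumping matrix (each column sums to 1).
#' @return n x m matrix.
#' @export
lumping_pinv <- function(M) {
  if (!all(M %in% c(0, 1)) || !all(colSums(M) == 1))
    stop("`M` is not a legal lumping matrix (0/1 with unit column sums)",
         call. = FALSE)
  t(M / rowSums(M))
}

#' Lump a compartmental model
#'
#' Builds the reduced system `d y_hat/dt = K_hat y_hat` with
#' `K_hat = M K M+` and `y_hat(0) = M y0`. The lumped volume of a block is
#' the sum of its members' volumes; the output block is the block containing
#' the original output state.
#'
#' @param model a [compartmental_model()].
#' @param partition a [lumping_partition()] on the model's states.
#' @return object of class `lumped_model`: list with `K_hat`, `blocks`,
#'   `block_names`, `y0_hat`, `output_block`, `volumes_hat`, `partition`,
#'   `m`. Use [as_compartmental_model()] to simulate it.
#' @examples
#' m <- compartmental_model(matrix(c(-1, 1, 0.5, -0.5), 2, 2), y0 = c(1, 0))
#' lump_model(m, lumping_partition(c(1, 1)))
#' @export
lump_model <- function(model, partition) {
  stopifnot(inherits(model, "compartmental_model"),
            inherits(partition, "lumping_partition"))
  if (partition$n != model$n)
    stop("partition is over ", partition$n, " states but the model has ",
         model$n, call. = FALSE)
  g <- partition$block_of
  m <- partition$m
  sizes <- tabulate(g, m)
  # K_hat = M K M+ : sum rows within blocks, average columns within blocks
  R <- rowsum(model$K, g, reorder = TRUE)
  K_hat <- t(rowsum(t(R), g, reorder = TRUE) / sizes)
  y0_hat <- as.numeric(rowsum(model$y0, g, reorder = TRUE))
  block_names <- vapply(partition$blocks, function(ix)
    paste(model$state_names[ix], collapse = "+"), character(1))
  dimnames(K_hat) <- list(block_names, block_names)
  names(y0_hat) <- block_names
  volumes_hat <- if (is.null(model$volumes)) NULL
                 else as.numeric(rowsum(model$volumes, g, reorder = TRUE))
  structure(list(K_hat = K_hat, blocks = partition$blocks,
                 block_names = block_names, y0_hat = y0_hat,
                 output_block = g[model$output_state],
                 volumes_hat = volumes_hat, partition = partition, m = m),
            class = "lumped_model")
}

#' @export
print.lumped_model <- function(x, ...) {
  cat("<lumped_model> m = ", x$m, " lumped states\n", sep = "")
  for (b in seq_len(x$m))
    cat("  ", b, if (b == x$output_block) " (output)" else "", ": ",
        x$block_names[b], "\n", sep = "")
  invisible(x)
}

#' Coerce to a compartmental model
#'
#' A lumped model is itself a linear compartmental system and can be
#' simulated with the same machinery. The mass-balance check is skipped:
#' lumping does not in general preserve volume-weighted mass balance exactly.
#'
#' @param x object to coerce.
#' @param ... unused.
#' @return a [compartmental_model()].
#' @export
as_compartmental_model <- function(x, ...) UseMethod("as_compartmental_model")

#' @export
as_compartmental_model.compartmental_model <- function(x, ...) x

#' @export
as_compartmental_model.lumped_model <- function(x, ...) {
  compartmental_model(x$K_hat, state_names = x$block_names,
                      volumes = x$volumes_hat, output_state = x$output_block,
                      y0 = x$y0_hat, check_balance = FALSE)
}

#' Physiological parameters of lumped blocks
#'
#' Aggregates per-tissue physiological parameters over the blocks of a
#' partition: lumped volume is the sum of member volumes, lumped flow the sum
#' of member flows, and the lumped partition coefficient is the
#' volume-weighted mean `sum(V_i Kp_i) / sum(V_i)` — the unique choice that
#' preserves the steady-state amount of drug in the merged tissue. The Kp
#' aggregation rule used is recorded in the `kp_rule` attribute
#' (`"volume-weighted"`).
#'
#' Blocks that mix tissues with blood, lung, or sub-compartment states have
#' no defined perfusion parameters: `Q` and `Kp` are reported as `NA` for
#' such blocks (volume is still the member sum).
#'
#' @param params a [physiological_parameters()] table.
#' @param partition a [lumping_partition()] over the rows of `params`.
#' @return data frame with one row per block: `block`, `members`, `V`, `Q`,
#'   `Kp`.
#' @export
lumped_physiological_parameters <- function(params, partition) {
  if (!inherits(params, "physiological_parameters"))
    params <- physiological_parameters(params)
  stopifnot(inherits(partition, "lumping_partition"))
  if (partition$n != nrow(params))
    stop("partition size does not match parameter table", call. = FALSE)
  out <- data.frame(block = seq_len(partition$m),
                    members = vapply(partition$blocks, function(ix)
                      paste(params$name[ix], collapse = "+"), character(1)),
                    V = NA_real_, Q = NA_real_, Kp = NA_real_)
  for (b in seq_len(partition$m)) {
    ix <- partition$blocks[[b]]
    out$V[b] <- sum(params$V[ix])
    if (all(params$type[ix] == "tissue")) {
      out$Q[b] <- sum(params$Q[ix])
      out$Kp[b] <- sum(params$V[ix] * params$Kp[ix]) / sum(params$V[ix])
    }
  }
  attr(out, "kp_rule") <- "volume-weighted"
  out
}
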