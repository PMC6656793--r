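#' Stirling number of the second kind
#'
#' Number of set partitions of `n` items into exactly `k` nonempty blocks;
#' this is the size of the constrained search space at each level of the
#' incremental lumping search.
#'
#' @param n item count.
#' @param k block count.
#' @return numeric (exact for values representable as doubles).
#' @export
stirling2 <- function(n, k) {
  if (k < 0 || k > n) return(0)
  if (n == 0) return(1)
  S <- numeric(k + 1)  # S[j+1] = S(i, j)
  S[1] <- 1
  for (i in seq_len(n)) {
    new <- numeric(k + 1)
    for (j in seq_len(min(i, k))) {
      new[j + 1] <- j * S[j + 1] + S[j]
    }
    S <- new
    S[1] <- 0
  }
  S[k + 1]
}

#' Iterator over constrained set partitions
#'
#' Enumerates every set partition of the free states (those not in
#' `constrained`) into `blocks - length(constrained)` nonempty blocks; each
#' constrained state sits in its own singleton block. Partitions are visited
#' in lexicographic restricted-growth-string order over the free states, each
#' exactly once (no duplicates under block relabelling); the total count is
#' the Stirling number `stirling2(n_free, blocks - n_constrained)`.
#'
#' Returned as a closure-based iterator so the full space is never held in
#' memory (the 17-state model at m = 4 already has ~7.1 million partitions).
#'
#' @param n number of states.
#' @param blocks total number of blocks m.
#' @param constrained indices of states forced into singleton blocks.
#' @return list with function `next_partition()`, returning an integer
#'   block-assignment vector of length `n` (canonical labels) or `NULL` when
#'   exhausted, and `size`, the total number of partitions.
#' @export
partition_iterator <- function(n, blocks, constrained = integer()) {
  constrained <- sort(unique(as.integer(constrained)))
  free <- setdiff(seq_len(n), constrained)
  Fn <- length(free)
  k <- blocks - length(constrained)
  size <- if (Fn == 0) as.numeric(k == 0) else stirling2(Fn, k)

  if (Fn == 0 || k < 1 || k > Fn) {
    done <- !(Fn == 0 && k == 0)
    return(list(next_partition = function() {
      if (done) return(NULL)
      done <<- TRUE
      assemble_assignment(n, free, integer(0), constrained)
    }, size = size))
  }

  a <- NULL  # current RGS over free states, labels 0..k-1
  advance <- function() {
    if (is.null(a)) {
      a <<- rep(0L, Fn)
      # lexicographically smallest RGS with exactly k blocks:
      # introduce the missing labels at the tail
      if (k > 1) a[(Fn - k + 2):Fn] <<- 1:(k - 1)
      return(TRUE)
    }
    repeat {
      # successor among RGS with max label <= k-1
      i <- Fn
      while (i >= 2) {
        cap <- min(max(a[seq_len(i - 1)]) + 1L, k - 1L)
        if (a[i] < cap) break
        i <- i - 1L
      }
      if (i < 2) return(FALSE)
      a[i] <<- a[i] + 1L
      if (i < Fn) a[(i + 1):Fn] <<- 0L
      if (length(unique(a)) == k) return(TRUE)
    }
  }
  list(next_partition = function() {
    if (!advance()) return(NULL)
    assemble_assignment(n, free, a, constrained)
  }, size = size)
}

# combine free-state RGS (0-based) and constrained singletons into one
# canonical assignment over all n states
assemble_assignment <- function(n, free, a, constrained) {
  g <- integer(n)
  g[free] <- a + length(constrained) + 1L
  g[constrained] <- seq_along(constrained)
  canonical_labels(g)
}

#' List all constrained set partitions
#'
#' Convenience wrapper around [partition_iterator()] that materialises every
#' partition as a [lumping_partition()]. Refuses spaces larger than
#' `max_size` to avoid accidental memory blow-ups.
#'
#' @inheritParams partition_iterator
#' @param max_size largest space this function will materialise.
#' @return list of `lumping_partition` objects.
#' @export
enumerate_constrained_partitions <- function(n, blocks,
                                             constrained = integer(),
                                             max_size = 1e6) {
  it <- partition_iterator(n, blocks, constrained)
  if (it$size > max_size)
    stop("partition space has ", it$size, " elements; use partition_iterator()",
         call. = FALSE)
  out <- vector("list", it$size)
  i <- 0L
  repeat {
    g <- it$next_partition()
    if (is.null(g)) break
    i <- i + 1L
    out[[i]] <- lumping_partition(g, constrained = constrained)
  }
  out[seq_len(i)]
}

#' Draw a uniformly random legal partition
#'
#' Samples a set partition of the free states into exactly `blocks -
#' length(constrained)` nonempty blocks, uniformly over set partitions:
#' labelled assignments are drawn uniformly and rejected until surjective,
#' which is uniform on partitions because every partition corresponds to the
#' same number of labelled assignments. Reproducible under [set.seed()].
#'
#' @inheritParams partition_iterator
#' @return a [lumping_partition()].
#' @export
sample_random_partition <- function(n, blocks, constrained = integer()) {
  constrained <- sort(unique(as.integer(constrained)))
  free <- setdiff(seq_len(n), constrained)
  k <- blocks - length(constrained)
  if (k < 1 || k > length(free))
    stop("infeasible block count: ", blocks, " blocks for ", length(free),
         " free states with ", length(constrained), " constrained",
         call. = FALSE)
  repeat {
    a <- sample.int(k, length(free), replace = TRUE)
    if (length(unique(a)) == k) break
  }
  g <- integer(n)
  g[constrained] <- seq_along(constrained)
  g[free] <- a + length(constrained)
  lumping_partition(g, constrained = constrained)
}

# propose a neighbour: move one free state to a different non-constrained
# block without emptying its source block; returns NULL if no legal move
propose_neighbour <- function(block_of, free, m, forbidden = integer()) {
  sizes <- tabulate(block_of, m)
  movable <- free[sizes[block_of[free]] > 1L]
  if (length(movable) == 0) return(NULL)
  s <- movable[sample.int(length(movable), 1L)]
  targets <- setdiff(seq_len(m), c(block_of[s], forbidden))
  if (length(targets) == 0) return(NULL)
  block_of[s] <- targets[sample.int(length(targets), 1L)]
  block_of
}
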