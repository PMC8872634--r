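#' Degree-preserving edge-swap randomization
#'
#' Randomizes a network by repeated directed double-edge swaps
#' (a->b, c->d) => (a->d, c->b), which conserve every node's in- and
#' out-degree. Swaps that would create a self-loop or a duplicate edge are
#' rejected. Swapping continues until at least `min_swapped_frac` of the
#' original edges are absent from the shuffled network, the standard null
#' model for motif enrichment.
#'
#' @param net a `grn` object with at least 2 edges.
#' @param min_swapped_frac required fraction of original edges replaced
#'   (default 0.8).
#' @param max_attempts attempt budget before giving up (default scales
#'   with edge count).
#' @return a shuffled `grn` with identical degree sequences, with
#'   attribute `frac_swapped` giving the achieved fraction.
#' @export
degree_preserving_shuffle <- function(net, min_swapped_frac = 0.8,
                                      max_attempts = NULL) {
  stopifnot_grn(net)
  m <- nrow(net$edges)
  if (m < 2L) stop("need at least 2 edges to shuffle")
  if (min_swapped_frac <= 0 || min_swapped_frac > 1)
    stop("`min_swapped_frac` must be in (0, 1]")
  if (is.null(max_attempts)) max_attempts <- 1000 * m + 10000
  res <- swap_shuffle_cpp(length(net$nodes), net$edges[, 1L],
                          net$edges[, 2L], min_swapped_frac, max_attempts)
  if (res$frac_swapped < min_swapped_frac)
    stop(sprintf(
      "could not swap %.0f%% of edges (achieved %.1f%%); graph too rigid",
      100 * min_swapped_frac, 100 * res$frac_swapped))
  out <- grn(cbind(res$from, res$to), nodes = net$nodes)
  attr(out, "frac_swapped") <- res$frac_swapped
  out
}

#' Motif enrichment Z-scores against a shuffled null ensemble
#'
#' For each of the five motif classes, compares the observed instance
#' count with its distribution over an ensemble of independent
#' degree-preserving shuffles of the original network:
#' `z = (n_real - mu_shuffled) / sigma_shuffled`. An empirical two-sided
#' p-value (fraction of null counts at least as far from the null mean)
#' is reported alongside.
#'
#' @param net a `grn` object.
#' @param n_shuffles number of null networks (default 10000, as used for
#'   the biological networks; 1000 is usually sufficient for generated
#'   networks).
#' @param min_swapped_frac passed to [degree_preserving_shuffle].
#' @return a data frame of class `motif_enrichment` with columns
#'   `motif`, `n_real`, `mu`, `sigma`, `z`, `p`. Degenerate null
#'   distributions (`sigma == 0`) yield `z` of `Inf`, `-Inf` or 0 by the
#'   sign of `n_real - mu`, flagged in the `degenerate` column.
#' @export
motif_zscores <- function(net, n_shuffles = 10000, min_swapped_frac = 0.8) {
  stopifnot_grn(net)
  if (n_shuffles < 2L) stop("need at least 2 shuffles")
  n <- length(net$nodes)
  n_real <- census5_cpp(n, net$edges[, 1L], net$edges[, 2L])
  m <- nrow(net$edges)
  max_attempts <- 1000 * m + 10000

  null_counts <- matrix(0L, n_shuffles, 5L)
  for (s in seq_len(n_shuffles)) {
    sh <- swap_shuffle_cpp(n, net$edges[, 1L], net$edges[, 2L],
                           min_swapped_frac, max_attempts)
    if (sh$frac_swapped < min_swapped_frac)
      stop(sprintf("shuffle %d achieved only %.1f%% swapped edges",
                   s, 100 * sh$frac_swapped))
    null_counts[s, ] <- census5_cpp(n, sh$from, sh$to)
  }
  mu <- colMeans(null_counts)
  sigma <- apply(null_counts, 2L, stats::sd)
  diff <- as.numeric(n_real) - mu
  z <- ifelse(sigma > 0, diff / sigma,
              ifelse(diff > 0, Inf, ifelse(diff < 0, -Inf, 0)))
  p <- vapply(1:5, function(k) {
    mean(abs(null_counts[, k] - mu[k]) >= abs(diff[k]))
  }, numeric(1))
  out <- data.frame(
    motif = names(n_real),
    n_real = as.integer(n_real),
    mu = mu,
    sigma = sigma,
    z = z,
    p = p,
    degenerate = sigma == 0,
    row.names = NULL
  )
  class(out) <- c("motif_enrichment", "data.frame")
  attr(out, "n_shuffles") <- n_shuffles
  out
}

#' Average nearest-neighbour degree
#'
#' For each non-isolated node, the mean total (in + out) degree of its
#' neighbours, where the neighbour set is the union of predecessors and
#' successors. Used as a diagnostic that degree-preserving shuffling keeps
#' the degree-degree correlation structure of the original network.
#'
#' @param net a `grn` object.
#' @return named numeric vector over non-isolated nodes.
#' @export
avg_nearest_neighbor_degree <- function(net) {
  stopifnot_grn(net)
  n <- length(net$nodes)
  deg <- in_degrees(net) + out_degrees(net)
  nbr <- vector("list", n)
  for (e in seq_len(nrow(net$edges))) {
    u <- net$edges[e, 1L]; v <- net$edges[e, 2L]
    nbr[[u]] <- c(nbr[[u]], v)
    nbr[[v]] <- c(nbr[[v]], u)
  }
  res <- vapply(seq_len(n), function(i) {
    nb <- unique(nbr[[i]])
    if (length(nb) == 0L) return(NA_real_)
    mean(deg[nb])
  }, numeric(1))
  names(res) <- net$nodes
  res[!is.na(res)]
}
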