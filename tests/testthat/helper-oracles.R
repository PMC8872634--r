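# Independent oracles used across the suite.

# random simple digraph: each ordered non-self pair present with prob p
# (reciprocal pairs allowed, exercising the census exclusion rule)
random_digraph <- function(n, p) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  grn(as.matrix(pairs[keep, , drop = FALSE]),
      nodes = paste0("G", seq_len(n) - 1L))
}

# brute-force census: scan all node triples with classify_triad
brute_force_census <- function(net) {
  n <- length(net$nodes)
  counts <- c(ffl = 0L, cascade = 0L, fan_in = 0L, fan_out = 0L, cycle = 0L)
  if (n < 3L) return(counts)
  triples <- utils::combn(n, 3L)
  for (k in seq_len(ncol(triples))) {
    cl <- classify_triad(net, triples[, k])
    if (!is.na(cl)) counts[cl] <- counts[cl] + 1L
  }
  counts
}

# igraph triad census, mapped to the five recognised classes
igraph_census5 <- function(net) {
  tc <- igraph::triad_census(as_igraph(net))
  # order: 003 012 102 021D 021U 021C 111D 111U 030T 030C 201 120D ...
  c(ffl = tc[9], cascade = tc[6], fan_in = tc[5], fan_out = tc[4],
    cycle = tc[10])
}

# degree sequences as a canonical comparable object
degree_pairs <- function(net) {
  n <- length(net$nodes)
  cbind(tabulate(net$edges[, 1L], n), tabulate(net$edges[, 2L], n))
}

edge_set_keys <- function(net) {
  n <- length(net$nodes)
  sort((net$edges[, 1L] - 1) * n + net$edges[, 2L])
}
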