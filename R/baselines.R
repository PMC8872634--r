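#' Uniform random directed graph with exact sparsity
#'
#' Samples exactly `round(sparsity * n)` distinct directed edges
#' uniformly without replacement from all ordered non-self pairs. The
#' binary uniform random model used as the least-structured reference.
#'
#' @param n number of nodes.
#' @param sparsity average links per node.
#' @return a `grn` object.
#' @export
rand_g <- function(n, sparsity) {
  m <- round(sparsity * n)
  if (m > n * (n - 1)) stop("infeasible sparsity for n nodes")
  nodes <- paste0("G", seq_len(n) - 1L)
  if (m == 0L) return(grn(NULL, nodes = nodes))
  # ordered non-self pairs indexed 0..n(n-1)-1
  k <- sample(n * (n - 1), m) - 1L
  from <- k %/% (n - 1L) + 1L
  r <- k %% (n - 1L) + 1L
  to <- ifelse(r >= from, r + 1L, r)
  grn(cbind(from, to), nodes = nodes)
}

#' Random directed acyclic graph with exact sparsity
#'
#' As [rand_g], but edges are only sampled from pairs `(i, j)` with `i`
#' before `j` in a random topological order, so the result is acyclic by
#' construction (its adjacency matrix in that order is strictly
#' triangular, hence nilpotent).
#'
#' @inheritParams rand_g
#' @return an acyclic `grn` object.
#' @export
dag <- function(n, sparsity) {
  m <- round(sparsity * n)
  if (m > n * (n - 1) / 2) stop("infeasible sparsity for an acyclic graph")
  nodes <- paste0("G", seq_len(n) - 1L)
  if (m == 0L) return(grn(NULL, nodes = nodes))
  ord <- sample.int(n)
  k <- sample(n * (n - 1) / 2, m)
  # unrank k-th pair (i < j) of 1..n; correct any floating-point slip
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  j <- j - (k <= (j - 1) * (j - 2) / 2)
  j <- j + (k > j * (j - 1) / 2)
  i <- k - (j - 1) * (j - 2) / 2
  grn(cbind(ord[i], ord[j]), nodes = nodes)
}

#' Directed scale-free graph with controlled sparsity
#'
#' A Bollobas-style directed scale-free growth process (each step adds
#' either a new node with an edge to an existing node chosen by
#' in-degree, a new node with an edge from an existing node chosen by
#' out-degree, or an edge between existing nodes), simplified to forbid
#' self-loops and duplicate edges, then passed through [adjust_sparsity]
#' so the edge count is exactly `round(sparsity * n)`.
#'
#' @inheritParams rand_g
#' @param alpha,beta,gamma probabilities of the three growth events
#'   (new node <- existing; existing <- existing; existing <- new node);
#'   must sum to 1.
#' @param delta_in,delta_out additive degree smoothing.
#' @return a `grn` object.
#' @export
scale_free_directed <- function(n, sparsity, alpha = 0.41, beta = 0.54,
                                gamma = 0.05, delta_in = 0.2,
                                delta_out = 0) {
  if (n < 3) stop("need n >= 3")
  if (abs(alpha + beta + gamma - 1) > 1e-9)
    stop("alpha + beta + gamma must sum to 1")
  target_m <- round(sparsity * n)
  nodes_n <- 3L
  from <- c(1L, 2L)
  to <- c(2L, 3L)
  indeg <- c(0L, 1L, 1L)
  outdeg <- c(1L, 1L, 0L)
  has <- logical(as.double(n) * n)
  has[(from - 1) * n + to] <- TRUE
  guard <- 0L
  while ((nodes_n < n || length(from) < target_m) && guard < 200L * n) {
    guard <- guard + 1L
    r <- stats::runif(1)
    if (r < alpha && nodes_n < n) {
      # new node -> existing target by in-degree
      v <- sample_weighted(seq_len(nodes_n), indeg[seq_len(nodes_n)] + delta_in)
      nodes_n <- nodes_n + 1L
      u <- nodes_n
      indeg[u] <- 0L; outdeg[u] <- 0L
    } else if (r < alpha + beta) {
      # edge between existing nodes: source by out-degree, target by in-degree
      u <- sample_weighted(seq_len(nodes_n),
                           outdeg[seq_len(nodes_n)] + delta_out + 1e-9)
      v <- sample_weighted(seq_len(nodes_n), indeg[seq_len(nodes_n)] + delta_in)
      if (u == v || has[(u - 1) * n + v]) next
    } else if (nodes_n < n) {
      # existing source by out-degree -> new node
      u <- sample_weighted(seq_len(nodes_n),
                           outdeg[seq_len(nodes_n)] + delta_out + 1e-9)
      nodes_n <- nodes_n + 1L
      v <- nodes_n
      indeg[v] <- 0L; outdeg[v] <- 0L
    } else next
    from <- c(from, u)
    to <- c(to, v)
    has[(u - 1) * n + v] <- TRUE
    outdeg[u] <- outdeg[u] + 1L
    indeg[v] <- indeg[v] + 1L
  }
  net <- grn(cbind(from, to), nodes = paste0("G", seq_len(n) - 1L))
  adjust_sparsity(net, sparsity)
}

#' Synthetic FFL-rich seed network
#'
#' Builds an FFL-rich directed graph for nucleating [fflatt_generate]
#' when no biological input network is supplied: starting from a single
#' FFL triangle, each added node is either attached below an edge of an
#' existing FFL (creating a new FFL that shares two nodes with its
#' parent) or attached as a plain preferential-attachment leaf. All FFLs
#' created this way are connected via shared nodes, so
#' [extract_ffl_nucleus] always succeeds, and at least `n / 10` FFLs are
#' guaranteed.
#'
#' This generator is a synthetic stand-in for a literature-curated
#' transcriptional network; its FFL-sharing structure mirrors what is
#' observed in such networks (essentially all FFLs sharing nodes).
#'
#' @param n number of nodes (at least 20).
#' @param ffl_frac fraction of node additions that create a new FFL
#'   (default 0.35).
#' @return a `grn` object.
#' @export
synthetic_seed_network <- function(n = 200, ffl_frac = 0.35) {
  if (n < 20) stop("need n >= 20")
  recs <- matrix(c(1L, 2L, 3L), ncol = 3L)
  from <- c(1L, 2L, 1L)
  to <- c(2L, 3L, 3L)
  outdeg <- c(2L, 1L, 0L)
  nn <- 3L
  min_ffl <- ceiling(n / 10)
  while (nn < n) {
    need_ffl <- (nrow(recs) < min_ffl) &&
      (n - nn <= min_ffl - nrow(recs))  # force quota if running out of nodes
    if (need_ffl || stats::runif(1) < ffl_frac) {
      r <- sample.int(nrow(recs), 1L)
      ed <- matrix(c(recs[r, 1L], recs[r, 2L],
                     recs[r, 2L], recs[r, 3L],
                     recs[r, 1L], recs[r, 3L]), ncol = 2L, byrow = TRUE)
      k <- sample.int(3L, 1L)
      u <- ed[k, 1L]; v <- ed[k, 2L]
      nn <- nn + 1L
      from <- c(from, u, v)
      to <- c(to, nn, nn)
      outdeg[u] <- outdeg[u] + 1L
      outdeg[v] <- outdeg[v] + 1L
      outdeg[nn] <- 0L
      recs <- rbind(recs, c(u, v, nn))
    } else {
      elig <- which(outdeg[seq_len(nn)] >= 1L)
      g <- sample_weighted(elig, outdeg[elig])
      nn <- nn + 1L
      from <- c(from, g)
      to <- c(to, nn)
      outdeg[g] <- outdeg[g] + 1L
      outdeg[nn] <- 0L
    }
  }
  grn(cbind(from, to), nodes = paste0("G", seq_len(n) - 1L))
}
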