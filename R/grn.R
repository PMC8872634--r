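#' Construct a directed gene regulatory network graph
#'
#' A `grn` is a simple directed graph: no self-loops, no duplicate edges,
#' every edge endpoint in the node set. Nodes are identified by character
#' labels; edges are stored as an integer matrix of indices into the node
#' vector. This is the shared container for the generators, the motif
#' census and the stability analysis.
#'
#' @param edges two-column matrix or data frame of (regulator, target)
#'   pairs, either character labels or integer indices into `nodes`.
#' @param nodes optional character vector of node labels. Defaults to the
#'   labels appearing in `edges`. Isolated nodes can be included by
#'   passing them here.
#' @param collapse if `TRUE`, silently drop duplicate edges and self-loops
#'   (with a message of how many); if `FALSE`, either is an error.
#' @return an object of class `grn` with elements `nodes` (character) and
#'   `edges` (integer matrix with columns `from`, `to`).
#' @export
grn <- function(edges, nodes = NULL, collapse = FALSE) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) < 2L)
    stop("`edges` must be a two-column matrix of (regulator, target) pairs")
  edges <- edges[, 1:2, drop = FALSE]

  if (is.character(edges) || is.factor(edges)) {
    labs <- as.character(edges)
    if (is.null(nodes)) nodes <- unique(labs)
    nodes <- as.character(nodes)
    idx <- match(labs, nodes)
    if (anyNA(idx)) stop("edge endpoint not present in `nodes`")
    edges <- matrix(idx, ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (is.null(nodes)) {
      n <- if (nrow(edges)) max(edges) else 0L
      nodes <- if (n > 0L) paste0("G", seq_len(n) - 1L) else character(0)
    }
    nodes <- as.character(nodes)
    if (nrow(edges) && (min(edges) < 1L || max(edges) > length(nodes)))
      stop("edge index out of range of `nodes`")
  }
  colnames(edges) <- c("from", "to")

  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    if (!collapse) stop("self-loops are not allowed in a grn")
    message(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- edge_key(edges, length(nodes))
  dup <- duplicated(key)
  if (any(dup)) {
    if (!collapse) stop("duplicate edges are not allowed in a grn")
    message(sum(dup), " duplicate edge(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges), class = "grn")
}

edge_key <- function(edges, n) {
  (as.double(edges[, 1L]) - 1) * n + as.double(edges[, 2L])
}

#' @export
print.grn <- function(x, ...) {
  cat("grn: directed network with", length(x$nodes), "nodes and",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    s <- nrow(x$edges) / length(x$nodes)
    cat("  sparsity (edges per node):", format(round(s, 3)), "\n")
  }
  invisible(x)
}

#' Number of nodes / edges in a network
#' @param net a `grn` object.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

out_degrees <- function(net) {
  tabulate(net$edges[, 1L], nbins = length(net$nodes))
}

in_degrees <- function(net) {
  tabulate(net$edges[, 2L], nbins = length(net$nodes))
}

stopifnot_grn <- function(net) {
  if (!inherits(net, "grn")) stop("expected a `grn` object")
  invisible(net)
}

#' Read a directed network from a TSV edge list
#'
#' Each non-comment line holds at least two whitespace-separated tokens,
#' regulator then target; extra columns are ignored. Lines starting with
#' `#` are comments. Duplicate lines are collapsed and self-loop lines
#' dropped, with a message reporting how many.
#'
#' @param path path to the edge-list file.
#' @return a [grn] object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(toks, length, 1L) < 2L
  if (any(bad))
    stop("malformed edge-list line ", lineno[which(bad)[1L]], " in ", path,
         " (need at least two columns)")
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  grn(cbind(from, to), collapse = TRUE)
}

#' Write a network as a TSV edge list
#'
#' @param net a `grn` object.
#' @param path output file path.
#' @return `path`, invisibly. Reading the file back reproduces the edge set.
#' @export
write_edge_list <- function(net, path) {
  stopifnot_grn(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# source\ttarget", con)
  if (nrow(net$edges))
    writeLines(paste(net$nodes[net$edges[, 1L]], net$nodes[net$edges[, 2L]],
                     sep = "\t"), con)
  invisible(path)
}

#' Convert between a network and its binary adjacency matrix
#'
#' The convention is "columns regulate rows": entry `(i, j)` is 1 iff the
#' edge j -> i is present, so the matrix left-multiplies a concentration
#' vector in the transcription model downstream.
#'
#' @param net a `grn` object.
#' @return for `to_adjacency`, a square 0/1 matrix with node labels as
#'   dimnames; for `from_adjacency`, a [grn].
#' @export
to_adjacency <- function(net) {
  stopifnot_grn(net)
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges))
    A[cbind(net$edges[, 2L], net$edges[, 1L])] <- 1L
  A
}

#' @rdname to_adjacency
#' @param A square binary matrix; `A[i, j] == 1` means j regulates i.
#'   A nonzero diagonal is forced to zero with a warning.
#' @export
from_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix")
  if (!all(A %in% c(0, 1)))
    stop("adjacency must be binary (0/1)")
  if (any(diag(A) != 0)) {
    warning("nonzero diagonal (self-loops) set to 0")
    diag(A) <- 0
  }
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- paste0("G", seq_len(nrow(A)) - 1L)
  idx <- which(A != 0, arr.ind = TRUE)
  grn(cbind(idx[, 2L], idx[, 1L]), nodes = nodes)
}

#' Topological degree summary of a network
#'
#' Sparsity is the average number of links per node, `|E|/N`; mean in- and
#' out-degree are additionally reported restricted to nodes with nonzero
#' degree of that kind, since regulatory networks have many pure targets
#' (zero out-degree) and a few pure sources.
#'
#' @param net a non-empty `grn` object.
#' @return a list of class `grn_degree_summary`: `n_nodes`, `n_edges`,
#'   `sparsity`, `mean_in_nonzero`, `mean_out_nonzero`, and `in_hist` /
#'   `out_hist` tables mapping degree to node count.
#' @export
degree_summary <- function(net) {
  stopifnot_grn(net)
  if (length(net$nodes) == 0L) stop("empty network")
  din <- in_degrees(net)
  dout <- out_degrees(net)
  structure(list(
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    sparsity = nrow(net$edges) / length(net$nodes),
    mean_in_nonzero = if (any(din > 0)) mean(din[din > 0]) else 0,
    mean_out_nonzero = if (any(dout > 0)) mean(dout[dout > 0]) else 0,
    in_hist = table(din),
    out_hist = table(dout)
  ), class = "grn_degree_summary")
}

#' @export
print.grn_degree_summary <- function(x, ...) {
  cat("nodes:", x$n_nodes, " edges:", x$n_edges, "\n")
  cat("sparsity (|E|/N):", format(round(x$sparsity, 3)), "\n")
  cat("mean in-degree  (nodes with in  >= 1):",
      format(round(x$mean_in_nonzero, 3)), "\n")
  cat("mean out-degree (nodes with out >= 1):",
      format(round(x$mean_out_nonzero, 3)), "\n")
  invisible(x)
}

#' Convert a grn to an igraph object
#' @param net a `grn` object.
#' @return an igraph directed graph with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot_grn(net)
  igraph::graph_from_data_frame(
    data.frame(from = net$nodes[net$edges[, 1L]],
               to = net$nodes[net$edges[, 2L]]),
    directed = TRUE,
    vertices = data.frame(name = net$nodes))
}
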