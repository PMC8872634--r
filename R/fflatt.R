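#' Rule probabilities for FFL-based preferential attachment
#'
#' The growth loop applies one of four attachment rules per iteration.
#' `p1` is the probability of plain preferential attachment (R1); the
#' complement `1 - p1` is the desired fraction of nodes participating in
#' FFL motifs and is split among the motif rules as
#' `p2 = (1 - p1) * 0.9`, `p3 = p4 = (1 - p1) * 0.05`.
#'
#' @param participation_target desired fraction of FFL-participating
#'   nodes, in (0, 1); sets `p1 = 1 - participation_target`.
#' @return a list of class `rule_probabilities` with `p1..p4`, summing
#'   to 1.
#' @export
derive_probabilities <- function(participation_target) {
  if (!is.numeric(participation_target) || length(participation_target) != 1L ||
      participation_target <= 0 || participation_target >= 1)
    stop("`participation_target` must be a single value in (0, 1)")
  p1 <- 1 - participation_target
  p2 <- (1 - p1) * 0.9
  p3 <- (1 - p1) * 0.05
  # complement form keeps the four probabilities summing to exactly 1 in
  # floating point (p4 equals (1-p1)*0.05 up to one ulp)
  p4 <- 1 - (p1 + p2 + p3)
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4),
            class = "rule_probabilities")
}

#' Parameters of the FFLatt generator
#'
#' @param n_nodes target network size (must exceed `nucleus_size`).
#' @param sparsity_target desired average number of links per node,
#'   `|E|/N`; the final edge count is exactly `round(sparsity_target *
#'   n_nodes)`.
#' @param participation_target desired fraction of nodes participating in
#'   at least one FFL; see [derive_probabilities].
#' @param gamma exponent of the preferential-attachment kernel
#'   (probability of attaching to regulator g proportional to
#'   out-degree(g)^gamma). Default 1 (linear preferential attachment).
#' @param k_max out-degree cap: nodes at the cap receive no new outgoing
#'   edges during growth. Default `max(10, ceiling(n_nodes / 10))`.
#' @param nucleus_size size of the seed subnetwork of node-sharing FFLs
#'   (default 20).
#' @param disrupt_cycles disrupt all three-node cycles after generation
#'   (used when mimicking the *E. coli* network, where 3-cycles are
#'   absent). Default `FALSE`.
#' @param deplete_motifs convert 3-cycles and a tenth of the FFL-disjoint
#'   cascades into FFLs after growth. Default `FALSE`.
#' @return a validated list of class `fflatt_params`.
#' @export
fflatt_params <- function(n_nodes, sparsity_target, participation_target,
                          gamma = 1, k_max = NULL, nucleus_size = 20,
                          disrupt_cycles = FALSE, deplete_motifs = FALSE) {
  if (is.null(k_max)) k_max <- max(10, ceiling(n_nodes / 10))
  stopifnot(nucleus_size >= 4, n_nodes > nucleus_size,
            sparsity_target > 0, k_max >= 2)
  if (participation_target <= 0 || participation_target >= 1)
    stop("`participation_target` must be in (0, 1)")
  if (round(sparsity_target * n_nodes) > n_nodes * (n_nodes - 1))
    stop("infeasible sparsity target")
  probs <- derive_probabilities(participation_target)
  structure(list(n_nodes = as.integer(n_nodes),
                 sparsity_target = sparsity_target,
                 participation_target = participation_target,
                 probs = probs,
                 gamma = gamma,
                 k_max = as.integer(k_max),
                 nucleus_size = as.integer(nucleus_size),
                 disrupt_cycles = isTRUE(disrupt_cycles),
                 deplete_motifs = isTRUE(deplete_motifs)),
            class = "fflatt_params")
}

## ---- mutable growth state ------------------------------------------------

# Growth never removes edges, so the state is append-only: edge vectors,
# degree counters, an O(1) edge-membership table, and the FFL library
# (records + per-node index of record ids).
new_growth_state <- function(net, library, gamma, k_max, n_max) {
  st <- new.env(parent = emptyenv())
  n0 <- length(net$nodes)
  m0 <- nrow(net$edges)
  cap <- max(4L * n_max + 100L, 2L * m0)
  st$n_max <- as.integer(n_max)
  st$gamma <- gamma
  st$kmax <- k_max
  st$n <- n0
  st$m <- m0
  st$from <- integer(cap)
  st$to <- integer(cap)
  st$from[seq_len(m0)] <- net$edges[, 1L]
  st$to[seq_len(m0)] <- net$edges[, 2L]
  st$outdeg <- integer(n_max)
  st$indeg <- integer(n_max)
  st$outdeg[seq_len(n_max)] <- tabulate(net$edges[, 1L], n_max)
  st$indeg[seq_len(n_max)] <- tabulate(net$edges[, 2L], n_max)
  st$has <- logical(as.double(n_max) * n_max)
  st$has[(net$edges[, 1L] - 1) * n_max + net$edges[, 2L]] <- TRUE
  st$rec_m <- integer(0)
  st$rec_i <- integer(0)
  st$rec_t <- integer(0)
  st$node_index <- vector("list", n_max)
  if (!is.null(library) && nrow(library)) {
    for (r in seq_len(nrow(library)))
      st_add_record(st, library[r, 1L], library[r, 2L], library[r, 3L])
  }
  st$fallbacks <- 0L
  st
}

st_has <- function(st, u, v) st$has[(u - 1) * st$n_max + v]

st_add_edge <- function(st, u, v) {
  if (st$m + 1L > length(st$from)) {
    st$from <- c(st$from, integer(length(st$from)))
    st$to <- c(st$to, integer(length(st$to)))
  }
  st$m <- st$m + 1L
  st$from[st$m] <- u
  st$to[st$m] <- v
  st$outdeg[u] <- st$outdeg[u] + 1L
  st$indeg[v] <- st$indeg[v] + 1L
  st$has[(u - 1) * st$n_max + v] <- TRUE
  invisible(st)
}

st_add_node <- function(st) {
  if (st$n >= st$n_max) stop("internal: node capacity exceeded")
  st$n <- st$n + 1L
  st$n
}

st_add_record <- function(st, m, i, t) {
  id <- length(st$rec_m) + 1L
  st$rec_m[id] <- m
  st$rec_i[id] <- i
  st$rec_t[id] <- t
  for (v in c(m, i, t))
    st$node_index[[v]] <- c(st$node_index[[v]], id)
  invisible(id)
}

st_to_grn <- function(st) {
  grn(cbind(st$from[seq_len(st$m)], st$to[seq_len(st$m)]),
      nodes = paste0("G", seq_len(st$n) - 1L))
}

st_record_edges <- function(st, id) {
  m <- st$rec_m[id]; i <- st$rec_i[id]; t <- st$rec_t[id]
  matrix(c(m, i, i, t, m, t), ncol = 2L, byrow = TRUE)
}

# sample one index from weights (safe for length-1 vectors)
sample_weighted <- function(idx, w) {
  if (length(idx) == 1L) return(idx)
  idx[sample.int(length(idx), 1L, prob = w)]
}

## ---- attachment rules (state versions) -----------------------------------

# R1: new node attached below an existing regulator, chosen with
# probability out-degree^gamma over nodes with 1 <= out-degree < k_max.
st_rule_r1 <- function(st) {
  od <- st$outdeg[seq_len(st$n)]
  elig <- which(od >= 1L & od < st$kmax)
  if (length(elig) == 0L) {
    elig <- which(od < st$kmax)  # fallback: uniform over uncapped nodes
    if (length(elig) == 0L) return(FALSE)
    g <- sample_weighted(elig, rep(1, length(elig)))
  } else {
    g <- sample_weighted(elig, od[elig]^st$gamma)
  }
  w <- st_add_node(st)
  st_add_edge(st, g, w)
  TRUE
}

st_pick_motif <- function(st) {
  nr <- length(st$rec_m)
  if (nr == 0L) return(NA_integer_)
  if (nr == 1L) return(1L)
  w <- vapply(seq_len(nr), function(r) {
    ids <- unique(c(st$node_index[[st$rec_m[r]]],
                    st$node_index[[st$rec_i[r]]],
                    st$node_index[[st$rec_t[r]]]))
    length(ids)  # == 1 + number of other records sharing a node
  }, numeric(1))
  sample_weighted(seq_len(nr), w)
}

# R2: new node w below an edge u -> v of a library motif; adds u -> w and
# v -> w, creating FFL (u, v, w) where w has only incoming edges (TTG).
st_rule_r2 <- function(st, retries = 100L) {
  for (a in seq_len(retries)) {
    r <- st_pick_motif(st)
    if (is.na(r)) return(FALSE)
    ed <- st_record_edges(st, r)
    ok <- st$outdeg[ed[, 1L]] < st$kmax & st$outdeg[ed[, 2L]] < st$kmax &
      !st$has[(ed[, 2L] - 1) * st$n_max + ed[, 1L]]  # keep edge unidirectional
    if (!any(ok)) next
    k <- sample_weighted(which(ok), rep(1, sum(ok)))
    u <- ed[k, 1L]; v <- ed[k, 2L]
    w <- st_add_node(st)
    st_add_edge(st, u, w)
    st_add_edge(st, v, w)
    st_add_record(st, u, v, w)
    return(TRUE)
  }
  FALSE
}

# R3: two edges x -> u and x -> v from an existing library node x onto an
# edge u -> v of a library motif, creating FFL (x, u, v) in which every
# node has at least one incoming and one outgoing edge (TTT).
st_rule_r3 <- function(st, retries = 100L) {
  lib_nodes <- which(lengths(st$node_index[seq_len(st$n)]) > 0L)
  if (length(lib_nodes) == 0L) return(FALSE)
  for (a in seq_len(retries)) {
    r <- st_pick_motif(st)
    if (is.na(r)) return(FALSE)
    ed <- st_record_edges(st, r)
    k <- sample.int(3L, 1L)
    u <- ed[k, 1L]; v <- ed[k, 2L]
    if (st$outdeg[v] < 1L || st$indeg[u] < 1L) next     # TTT typing
    cand <- lib_nodes[lib_nodes != u & lib_nodes != v]
    if (length(cand) == 0L) next
    od <- st$outdeg[cand]
    cand <- cand[st$indeg[cand] >= 1L & od >= 1L & od + 2L <= st$kmax]
    if (length(cand) == 0L) next
    base <- (cand - 1) * st$n_max
    free <- !st$has[base + u] & !st$has[base + v] &
      !st$has[(u - 1) * st$n_max + cand] & !st$has[(v - 1) * st$n_max + cand]
    cand <- cand[free]
    if (length(cand) == 0L) next
    x <- sample_weighted(cand, rep(1, length(cand)))
    st_add_edge(st, x, u)
    st_add_edge(st, x, v)
    st_add_record(st, x, u, v)
    return(TRUE)
  }
  FALSE
}

# R4: close a 2-path u -> v -> w spanning two library motifs that share v
# with the edge u -> w, creating FFL (u, v, w).
st_rule_r4 <- function(st, retries = 100L) {
  if (length(st$rec_m) < 2L) return(FALSE)
  for (a in seq_len(retries)) {
    r <- st_pick_motif(st)
    if (is.na(r)) return(FALSE)
    nodes_r <- c(st$rec_m[r], st$rec_i[r], st$rec_t[r])
    v <- nodes_r[sample.int(3L, 1L)]
    others <- setdiff(st$node_index[[v]], r)
    if (length(others) == 0L) next
    s <- others[sample.int(length(others), 1L)]
    # u: tail of an edge of record r ending at v
    us <- integer(0)
    if (v == st$rec_i[r]) us <- st$rec_m[r]
    if (v == st$rec_t[r]) us <- c(st$rec_m[r], st$rec_i[r])
    # w: head of an edge of record s starting at v
    ws <- integer(0)
    if (v == st$rec_m[s]) ws <- c(st$rec_i[s], st$rec_t[s])
    if (v == st$rec_i[s]) ws <- st$rec_t[s]
    if (length(us) == 0L || length(ws) == 0L) next
    u <- us[sample.int(length(us), 1L)]
    w <- ws[sample.int(length(ws), 1L)]
    if (u == w) next
    if (st_has(st, u, w) || st_has(st, w, u)) next
    if (st$outdeg[u] >= st$kmax) next
    if (st$indeg[u] < 1L || st$outdeg[w] < 1L) next     # TTT typing
    st_add_edge(st, u, w)
    st_add_record(st, u, v, w)
    return(TRUE)
  }
  FALSE
}

## ---- public rule wrappers (operate on grn + record matrix) ---------------

grn_library <- function(net, library) {
  if (is.null(library)) library <- motif_census(net)$ffl_records
  storage.mode(library) <- "integer"
  library
}

#' Apply one attachment rule to a network
#'
#' These are the single-step versions of the four growth rules, exposed
#' for inspection and testing; [fflatt_generate] drives them in a loop.
#' `rule_r1` adds a node below a preferentially chosen regulator;
#' `rule_r2` adds a node plus two edges forming a new FFL (TTG type);
#' `rule_r3` adds two edges among existing nodes forming a new FFL (TTT);
#' `rule_r4` adds one edge closing a 2-path across two node-sharing FFLs.
#'
#' @param net a `grn` object.
#' @param library integer matrix of FFL records (columns
#'   master/intermediate/target, node indices); defaults to the census of
#'   `net`.
#' @param gamma preferential-attachment exponent (R1).
#' @param k_max out-degree cap.
#' @return a list with elements `net` (the updated network), `library`
#'   (updated record matrix) and `applied` (logical: whether the rule
#'   found an eligible configuration).
#' @export
rule_r1 <- function(net, gamma = 1, k_max = Inf) {
  st <- new_growth_state(net, NULL, gamma, k_max, length(net$nodes) + 1L)
  ok <- st_rule_r1(st)
  list(net = st_to_grn(st), applied = ok)
}

#' @rdname rule_r1
#' @export
rule_r2 <- function(net, library = NULL, k_max = Inf) {
  library <- grn_library(net, library)
  st <- new_growth_state(net, library, 1, k_max, length(net$nodes) + 1L)
  ok <- st_rule_r2(st)
  list(net = st_to_grn(st), library = state_library(st), applied = ok)
}

#' @rdname rule_r1
#' @export
rule_r3 <- function(net, library = NULL, k_max = Inf) {
  library <- grn_library(net, library)
  st <- new_growth_state(net, library, 1, k_max, length(net$nodes))
  ok <- st_rule_r3(st)
  list(net = st_to_grn(st), library = state_library(st), applied = ok)
}

#' @rdname rule_r1
#' @export
rule_r4 <- function(net, library = NULL, k_max = Inf) {
  library <- grn_library(net, library)
  st <- new_growth_state(net, library, 1, k_max, length(net$nodes))
  ok <- st_rule_r4(st)
  list(net = st_to_grn(st), library = state_library(st), applied = ok)
}

state_library <- function(st) {
  cbind(master = st$rec_m, intermediate = st$rec_i, target = st$rec_t)
}

#' Sample an FFL record by its connectivity with other records
#'
#' Records are sampled with probability proportional to 1 plus the number
#' of other records sharing at least one node, so well-connected motifs
#' are extended more often but isolated motifs stay reachable.
#'
#' @param library integer matrix of FFL records.
#' @return the index of the sampled record row.
#' @export
pick_motif_by_connectivity <- function(library) {
  nr <- nrow(library)
  if (nr == 0L) stop("empty FFL library")
  if (nr == 1L) return(1L)
  node_ids <- sort(unique(as.vector(library)))
  idx <- lapply(node_ids, function(v) which(
    library[, 1L] == v | library[, 2L] == v | library[, 3L] == v))
  names(idx) <- node_ids
  w <- vapply(seq_len(nr), function(r) {
    length(unique(unlist(idx[as.character(library[r, ])])))
  }, numeric(1))
  sample_weighted(seq_len(nr), w)
}

## ---- nucleation ----------------------------------------------------------

#' Extract a nucleus of node-sharing FFLs from an input network
#'
#' Finds a connected cluster of FFL motifs (connected via shared nodes)
#' by breadth-first search over the FFL-overlap graph from a random
#' starting FFL, accumulating motifs until their node union reaches
#' `nucleus_size` or the cluster is exhausted, and returns the induced
#' subgraph on that node union. Every node of the result participates in
#' an FFL of the result.
#'
#' @param input_net a `grn` containing at least one FFL (e.g. a
#'   biological regulatory network, or [synthetic_seed_network]).
#' @param nucleus_size minimum number of nodes to accumulate (default 20).
#' @return a `grn`: the induced FFL-cluster subgraph, with original node
#'   labels.
#' @export
extract_ffl_nucleus <- function(input_net, nucleus_size = 20) {
  stopifnot_grn(input_net)
  cen <- motif_census(input_net)
  recs <- cen$ffl_records
  if (nrow(recs) == 0L)
    stop("input network contains no FFL; supply an FFL-rich seed network ",
         "(see synthetic_seed_network())")
  n <- length(input_net$nodes)
  node2rec <- vector("list", n)
  for (r in seq_len(nrow(recs)))
    for (v in recs[r, ]) node2rec[[v]] <- c(node2rec[[v]], r)

  start <- sample.int(nrow(recs), 1L)
  in_cluster <- rep(FALSE, nrow(recs))
  in_cluster[start] <- TRUE
  queue <- start
  nodes <- unique(as.vector(recs[start, , drop = FALSE]))
  while (length(queue) > 0L && length(nodes) < nucleus_size) {
    r <- queue[1L]
    queue <- queue[-1L]
    nb <- unique(unlist(node2rec[recs[r, ]]))
    nb <- nb[!in_cluster[nb]]
    for (s in nb) {
      if (length(nodes) >= nucleus_size) break
      in_cluster[s] <- TRUE
      queue <- c(queue, s)
      nodes <- unique(c(nodes, recs[s, ]))
    }
  }
  keep <- input_net$edges[, 1L] %in% nodes & input_net$edges[, 2L] %in% nodes
  sub <- input_net$edges[keep, , drop = FALSE]
  grn(cbind(match(sub[, 1L], nodes), match(sub[, 2L], nodes)),
      nodes = input_net$nodes[nodes])
}

## ---- sparsity adjustment and motif post-processing -----------------------

#' Adjust a network to an exact sparsity level
#'
#' Brings the edge count to exactly `round(sparsity_target * n)`. If the
#' network is too dense, edges are removed one at a time with probability
#' proportional to the out-degree of their source node, so links of
#' highly connected regulators are preferentially pruned. If too sparse,
#' new edges are added with the source sampled proportional to out-degree
#' (with +1 smoothing for nodes with no outgoing edges; sources at the
#' `k_max` cap are excluded while any uncapped source remains) and the
#' target uniform among current non-targets of that source.
#'
#' By default an addition rejects (with bounded retries) any target that
#' would close a new FFL instance, so the density step does not perturb
#' the FFL content that the attachment rules control; set
#' `avoid_new_ffl = FALSE` for unconstrained uniform targets.
#'
#' @param net a `grn` object.
#' @param sparsity_target desired average links per node.
#' @param protected_budget number of edges already spent by motif
#'   conversions (bookkeeping from [deplete_non_ffl_motifs]); recorded on
#'   the result as attribute `protected_budget`.
#' @param k_max out-degree cap applied to addition sources (default
#'   `Inf`).
#' @param avoid_new_ffl reject addition targets that would create a new
#'   FFL (default `TRUE`).
#' @param target_retries rejection-sampling budget per added edge before
#'   accepting an FFL-closing target anyway.
#' @return a `grn` with exactly `round(sparsity_target * n)` edges.
#' @export
adjust_sparsity <- function(net, sparsity_target, protected_budget = 0,
                            k_max = Inf, avoid_new_ffl = TRUE,
                            target_retries = 30L) {
  stopifnot_grn(net)
  n <- length(net$nodes)
  target_m <- round(sparsity_target * n)
  if (target_m > n * (n - 1)) stop("infeasible sparsity target")
  from <- net$edges[, 1L]
  to <- net$edges[, 2L]
  outdeg <- tabulate(from, n)

  if (length(from) > target_m) {
    while (length(from) > target_m) {
      k <- sample_weighted(seq_along(from), outdeg[from])
      outdeg[from[k]] <- outdeg[from[k]] - 1L
      from <- from[-k]
      to <- to[-k]
    }
  } else if (length(from) < target_m) {
    has <- logical(as.double(n) * n)
    has[(from - 1) * n + to] <- TRUE
    out_adj <- lapply(split(to, factor(from, levels = seq_len(n))), identity)
    in_adj <- lapply(split(from, factor(to, levels = seq_len(n))), identity)
    # would adding s -> t close any new FFL (as master->target,
    # master->intermediate, or intermediate->target edge)?
    closes_ffl <- function(s, t) {
      os <- out_adj[[s]]
      if (length(os) && any(has[(os - 1) * n + t])) return(TRUE)
      ot <- out_adj[[t]]
      if (length(ot) && any(has[(s - 1) * n + ot])) return(TRUE)
      is <- in_adj[[s]]
      if (length(is) && any(has[(is - 1) * n + t])) return(TRUE)
      FALSE
    }
    while (length(from) < target_m) {
      w <- pmax(outdeg, 1)
      w[outdeg >= k_max] <- 0
      if (all(w == 0)) w <- pmax(outdeg, 1)  # every source capped: relax
      src <- sample_weighted(seq_len(n), w)
      avail <- which(!has[(src - 1) * n + seq_len(n)])
      avail <- avail[avail != src]
      if (length(avail) == 0L) next
      tgt <- NA_integer_
      if (avoid_new_ffl) {
        for (a in seq_len(target_retries)) {
          cand <- avail[sample.int(length(avail), 1L)]
          if (!closes_ffl(src, cand)) {
            tgt <- cand
            break
          }
        }
      }
      if (is.na(tgt)) tgt <- avail[sample.int(length(avail), 1L)]
      from <- c(from, src)
      to <- c(to, tgt)
      has[(src - 1) * n + tgt] <- TRUE
      out_adj[[src]] <- c(out_adj[[src]], tgt)
      in_adj[[tgt]] <- c(in_adj[[tgt]], src)
      outdeg[src] <- outdeg[src] + 1L
    }
  }
  out <- grn(cbind(from, to), nodes = net$nodes)
  attr(out, "protected_budget") <- protected_budget
  out
}

# all directed 3-cycles as rows (a, b, c) with edges a->b, b->c, c->a,
# deduplicated to one row per triad
find_three_cycles <- function(from, to, n) {
  has <- logical(as.double(n) * n)
  has[(from - 1) * n + to] <- TRUE
  out_adj <- split(to, factor(from, levels = seq_len(n)))
  cyc <- list()
  for (e in seq_along(from)) {
    a <- from[e]; b <- to[e]
    for (cc in out_adj[[b]]) {
      if (cc == a) next
      if (has[(cc - 1) * n + a] && a < b && a < cc)  # canonical: a smallest
        cyc[[length(cyc) + 1L]] <- c(a, b, cc)
    }
  }
  if (length(cyc) == 0L) return(matrix(integer(0), ncol = 3L))
  do.call(rbind, cyc)
}

#' Disrupt all three-node cycles
#'
#' For each 3-cycle, deletes the within-cycle outgoing edge of the cycle
#' node with the highest global out-degree (ties broken at random) and
#' attaches a replacement edge from that node to a target sampled with
#' probability proportional to total degree + 1, rejecting self-loops,
#' duplicates and additions that would create a new 3-cycle. Used when
#' mimicking regulatory networks in which 3-cycles are absent.
#'
#' @param net a `grn` object.
#' @param max_tries rejection-sampling budget per replacement edge; if
#'   exhausted the edge is dropped without replacement (reported via
#'   attribute `dropped_edges`).
#' @return a `grn` with no 3-cycles.
#' @export
disrupt_three_cycles <- function(net, max_tries = 100L) {
  stopifnot_grn(net)
  n <- length(net$nodes)
  from <- net$edges[, 1L]
  to <- net$edges[, 2L]
  dropped <- 0L
  repeat {
    cyc <- find_three_cycles(from, to, n)
    if (nrow(cyc) == 0L) break
    tri <- cyc[1L, ]
    outdeg <- tabulate(from, n)
    od <- outdeg[tri]
    x <- tri[which(od == max(od))]
    if (length(x) > 1L) x <- x[sample.int(length(x), 1L)]
    # within-cycle outgoing edge of x: x -> succ(x) in the cycle a->b->c->a
    succ <- c(tri[2L], tri[3L], tri[1L])[match(x, tri)]
    k <- which(from == x & to == succ)[1L]
    from <- from[-k]
    to <- to[-k]
    # replacement from x, target ~ total degree + 1
    has <- logical(as.double(n) * n)
    has[(from - 1) * n + to] <- TRUE
    deg <- tabulate(from, n) + tabulate(to, n)
    placed <- FALSE
    for (a in seq_len(max_tries)) {
      t <- sample_weighted(seq_len(n), deg + 1)
      if (t == x || has[(x - 1) * n + t]) next
      # would x -> t close a new 3-cycle t -> y -> x?
      ys <- to[from == t]
      if (length(ys) && any(has[(ys - 1) * n + x])) next
      from <- c(from, x)
      to <- c(to, t)
      placed <- TRUE
      break
    }
    if (!placed) dropped <- dropped + 1L
  }
  out <- grn(cbind(from, to), nodes = net$nodes)
  attr(out, "dropped_edges") <- dropped
  out
}

#' Convert non-FFL motifs into FFLs
#'
#' Mimics the complete three-node motif profile of biological regulatory
#' networks, in which all non-FFL motifs are depleted. Every 3-cycle has
#' one edge reversed (chosen uniformly among edges whose reversal creates
#' neither a duplicate nor a reciprocal pair), turning it into an FFL.
#' Then up to one tenth of the cascades a -> b -> c that share no edge
#' with any FFL instance are closed with the edge a -> c, each creating a
#' new FFL. The number of closing edges added is returned so it can be
#' accounted for by [adjust_sparsity].
#'
#' @param net a `grn` object.
#' @return a list with `net` (the converted network) and `edges_consumed`
#'   (the number of cascade-closing edges added).
#' @export
deplete_non_ffl_motifs <- function(net) {
  stopifnot_grn(net)
  n <- length(net$nodes)
  from <- net$edges[, 1L]
  to <- net$edges[, 2L]

  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10L * n) break  # reversals keep re-creating cycles; stop
    cyc <- find_three_cycles(from, to, n)
    if (nrow(cyc) == 0L) break
    converted <- FALSE
    for (r in seq_len(nrow(cyc))) {
      tri <- cyc[r, ]
      ce_from <- tri
      ce_to <- c(tri[2L], tri[3L], tri[1L])
      has <- logical(as.double(n) * n)
      has[(from - 1) * n + to] <- TRUE
      ok <- !has[(ce_to - 1) * n + ce_from]  # reversal must not duplicate
      if (!any(ok)) next
      k <- which(ok)
      if (length(k) > 1L) k <- k[sample.int(length(k), 1L)]
      e <- which(from == ce_from[k] & to == ce_to[k])[1L]
      from[e] <- ce_to[k]
      to[e] <- ce_from[k]
      converted <- TRUE
      break  # recompute cycles after each conversion
    }
    if (!converted) break  # remaining cycles are stuck; leave them
  }

  # cascades edge-disjoint from every FFL
  cur <- grn(cbind(from, to), nodes = net$nodes)
  recs <- motif_census(cur)$ffl_records
  ffl_edges <- logical(as.double(n) * n)
  if (nrow(recs)) {
    ffl_edges[(recs[, 1L] - 1) * n + recs[, 2L]] <- TRUE
    ffl_edges[(recs[, 2L] - 1) * n + recs[, 3L]] <- TRUE
    ffl_edges[(recs[, 1L] - 1) * n + recs[, 3L]] <- TRUE
  }
  has <- logical(as.double(n) * n)
  has[(from - 1) * n + to] <- TRUE
  out_adj <- split(to, factor(from, levels = seq_len(n)))
  in_adj <- split(from, factor(to, levels = seq_len(n)))
  casc <- list()
  for (b in seq_len(n)) {
    for (a in in_adj[[b]]) {
      if (has[(b - 1) * n + a]) next
      for (cc in out_adj[[b]]) {
        if (cc == a || has[(cc - 1) * n + b]) next
        if (has[(a - 1) * n + cc] || has[(cc - 1) * n + a]) next
        if (ffl_edges[(a - 1) * n + b] || ffl_edges[(b - 1) * n + cc]) next
        casc[[length(casc) + 1L]] <- c(a, b, cc)
      }
    }
  }
  added <- 0L
  if (length(casc)) {
    quota <- floor(0.1 * length(casc))
    if (quota > 0L) {
      pick <- sample.int(length(casc), length(casc))
      for (k in pick) {
        if (added >= quota) break
        a <- casc[[k]][1L]; cc <- casc[[k]][3L]
        if (has[(a - 1) * n + cc] || has[(cc - 1) * n + a]) next
        from <- c(from, a)
        to <- c(to, cc)
        has[(a - 1) * n + cc] <- TRUE
        added <- added + 1L
      }
    }
  }
  list(net = grn(cbind(from, to), nodes = net$nodes), edges_consumed = added)
}

## ---- top-level generator -------------------------------------------------

#' Generate an FFL-enriched gene regulatory network graph
#'
#' Grows a directed network from a nucleus of node-sharing FFL motifs by
#' iterating the four attachment rules (see [rule_r1]) with the rule
#' probabilities derived from the participation target, until the target
#' node count is reached; then (optionally) converts non-FFL motifs,
#' adjusts the sparsity to exactly `round(sparsity_target * n_nodes)`
#' edges, and (optionally) disrupts remaining 3-cycles.
#'
#' @param params an [fflatt_params] object.
#' @param nucleus optional `grn` to use as the seed subnetwork; by
#'   default a nucleus of `params$nucleus_size` nodes is extracted from
#'   [synthetic_seed_network]. Supply
#'   `extract_ffl_nucleus(read_edge_list("..."), ...)` to nucleate from a
#'   biological network.
#' @return a `grn` with exactly `params$n_nodes` nodes (labelled
#'   `G0..G{N-1}`), carrying attributes `ffl_library` (the rule-created
#'   FFL records, an integer matrix of node indices), `params`, and
#'   `rule_fallbacks` (count of iterations where a motif rule found no
#'   eligible configuration and fell back to R1).
#' @export
fflatt_generate <- function(params, nucleus = NULL) {
  if (!inherits(params, "fflatt_params")) stop("expected `fflatt_params`")
  if (is.null(nucleus)) {
    seed_net <- synthetic_seed_network(max(200L, 10L * params$nucleus_size))
    nucleus <- extract_ffl_nucleus(seed_net, params$nucleus_size)
  }
  stopifnot_grn(nucleus)
  if (length(nucleus$nodes) > params$n_nodes)
    stop("nucleus larger than target size")
  library <- motif_census(nucleus)$ffl_records
  if (nrow(library) == 0L) stop("nucleus contains no FFL")

  st <- new_growth_state(nucleus, library, params$gamma, params$k_max,
                         params$n_nodes)
  p <- params$probs
  max_iter <- 60L * params$n_nodes
  iter <- 0L
  while (st$n < params$n_nodes && iter < max_iter) {
    iter <- iter + 1L
    r1 <- stats::runif(1)
    if (r1 <= p$p1) {
      st_rule_r1(st)
    } else {
      r2 <- stats::runif(1)
      ok <- if (r2 <= p$p2 / (1 - p$p1)) {
        st_rule_r2(st)
      } else if (stats::runif(1) <= 0.5) {
        st_rule_r3(st)
      } else {
        st_rule_r4(st)
      }
      if (!ok) {
        st$fallbacks <- st$fallbacks + 1L
        st_rule_r1(st)
      }
    }
  }
  if (st$n < params$n_nodes)
    stop("growth did not reach target size within the iteration budget")

  net <- st_to_grn(st)
  budget <- 0L
  if (params$deplete_motifs) {
    dep <- deplete_non_ffl_motifs(net)
    net <- dep$net
    budget <- dep$edges_consumed
  }
  net <- adjust_sparsity(net, params$sparsity_target,
                         protected_budget = budget, k_max = params$k_max)
  if (params$disrupt_cycles) net <- disrupt_three_cycles(net)

  attr(net, "ffl_library") <- state_library(st)
  attr(net, "params") <- params
  attr(net, "rule_fallbacks") <- st$fallbacks
  net
}

#' Audit the FFL library of a generated network
#'
#' Checks that every rule-created FFL record of a generated network still
#' has its three edges present (sparsity adjustment may prune edges, and
#' the census may additionally contain organically formed FFLs that were
#' never recorded).
#'
#' @param net a network from [fflatt_generate] (or any `grn`).
#' @param library integer record matrix; defaults to
#'   `attr(net, "ffl_library")`.
#' @return logical vector, one entry per record: all three edges present.
#' @export
audit_ffl_library <- function(net, library = attr(net, "ffl_library")) {
  stopifnot_grn(net)
  if (is.null(library)) stop("no FFL library found")
  n <- length(net$nodes)
  has <- logical(as.double(n) * n)
  has[(net$edges[, 1L] - 1) * n + net$edges[, 2L]] <- TRUE
  has[(library[, 1L] - 1) * n + library[, 2L]] &
    has[(library[, 2L] - 1) * n + library[, 3L]] &
    has[(library[, 1L] - 1) * n + library[, 3L]]
}
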