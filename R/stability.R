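#' Parameters of the transcription-allocation stability model
#'
#' The model assigns signed interaction strengths to the edges of a
#' binary network, computes the steady state of the RNA-polymerase
#' allocation dynamics `dc_i/dt ~ phi_i(c) - c_i` (the quasi-steady-state
#' reduction of the coupled mRNA/protein dynamics), and scores stability
#' by `lambda_M`, the maximal real part of the eigenvalues of the
#' gene-gene Jacobian `M = d phi / d c` at the fixed point: the system is
#' stable when `lambda_M < 1`.
#'
#' @param h Hill saturation coefficient (proteins needed to saturate DNA
#'   binding). Default 2.
#' @param K activation threshold concentration of the Hill function
#'   (shared scalar). Default `NULL`: use `1/N`, the natural scale of
#'   the allocation-fraction concentrations, so regulation stays
#'   responsive at every system size.
#' @param g0 basal effective gene copy number. Default 1.
#' @param gamma_bound maximal absolute link strength; strengths are drawn
#'   from a normal distribution truncated to `(0, gamma_bound]` in
#'   magnitude. Default 1.5.
#' @param gamma_sd pre-truncation standard deviation of link strengths.
#'   Default 0.5.
#' @param n_weight_reps number of link-strength redraws per graph.
#'   Default 10.
#' @param fp_tol convergence tolerance (max absolute change) of the
#'   fixed-point iteration. Default 1e-10.
#' @param fp_max_iter iteration cap. Default 10000.
#' @param damping damping factor of the fixed-point update
#'   `c <- (1 - d) c + d phi(c)`. Default 0.5.
#' @param g_floor positivity floor for the effective gene activity (the
#'   regulation product can go nonpositive for strong repression);
#'   clamped genes contribute zero derivative. Default 1e-6.
#' @param form form of the gene-activity equation: `"additive"`
#'   (`g = g0 + prod(1 + gamma f)`, basal activity plus regulated
#'   component; the default) or `"multiplicative"`
#'   (`g = g0 * prod(1 + gamma f)`).
#' @return a list of class `stability_params`.
#' @export
stability_params <- function(h = 2, K = NULL, g0 = 1, gamma_bound = 1.5,
                             gamma_sd = 0.5, n_weight_reps = 10,
                             fp_tol = 1e-10, fp_max_iter = 10000,
                             damping = 0.5, g_floor = 1e-6,
                             form = c("additive", "multiplicative")) {
  stopifnot(h >= 1, is.null(K) || K > 0, g0 > 0, gamma_bound > 0,
            g_floor > 0, damping > 0, damping <= 1)
  structure(list(h = h, K = K, g0 = g0, gamma_bound = gamma_bound,
                 gamma_sd = gamma_sd, n_weight_reps = n_weight_reps,
                 fp_tol = fp_tol, fp_max_iter = fp_max_iter,
                 damping = damping, g_floor = g_floor,
                 form = match.arg(form)),
            class = "stability_params")
}

# The concentrations are allocation fractions summing to 1, so the
# natural concentration scale is 1/N; when no activation threshold K is
# given it defaults to that scale, keeping the Hill functions responsive
# at any system size.
resolve_K <- function(params, n) {
  if (!is.null(params$K)) params$K else 1 / n
}

#' Hill activation function
#'
#' `hill(c) = c^h / (K^h + c^h)`: 0 at zero concentration, 1/2 at
#' `c = K`, saturating at 1.
#'
#' @param c nonnegative concentration (vectorised).
#' @param K threshold concentration.
#' @param h Hill coefficient.
#' @return values in `[0, 1]`.
#' @export
hill <- function(c, K, h) {
  if (any(c < 0)) stop("negative concentration")
  c^h / (K^h + c^h)
}

hill_deriv <- function(c, K, h) {
  h * K^h * c^(h - 1) / (K^h + c^h)^2
}

#' Assign signed interaction strengths to a network
#'
#' Each edge j -> i receives a strength `gamma_ij` whose magnitude is
#' drawn from `Normal(0, gamma_sd)` truncated to `(0, gamma_bound]`, with
#' a uniformly random half of the edges positive (activating) and the
#' other half negative (repressing); with an odd edge count the extra
#' edge is positive.
#'
#' @param net a `grn` with at least 2 edges.
#' @param params a [stability_params] object.
#' @return an object of class `interaction_weights`: list with `src`
#'   (regulator index j per edge), `tgt` (target index i), `w` (signed
#'   strength), `n` (number of genes).
#' @export
assign_weights <- function(net, params = stability_params()) {
  stopifnot_grn(net)
  m <- nrow(net$edges)
  if (m < 2L) stop("need at least 2 edges")
  mag <- numeric(0)
  while (length(mag) < m) {
    draw <- abs(stats::rnorm(2L * (m - length(mag)), 0, params$gamma_sd))
    draw <- draw[draw > 0 & draw <= params$gamma_bound]
    mag <- c(mag, draw)
  }
  mag <- mag[seq_len(m)]
  sgn <- rep(-1, m)
  sgn[sample.int(m, ceiling(m / 2))] <- 1
  structure(list(src = net$edges[, 1L], tgt = net$edges[, 2L],
                 w = mag * sgn, n = length(net$nodes)),
            class = "interaction_weights")
}

#' @export
print.interaction_weights <- function(x, ...) {
  cat("interaction weights:", length(x$w), "edges on", x$n, "genes;",
      sum(x$w > 0), "activating /", sum(x$w < 0), "repressing\n")
  invisible(x)
}

#' Dense gamma matrix of an interaction-weights object
#' @param weights an `interaction_weights` object.
#' @return square matrix with `gamma[i, j]` the strength of j -> i.
#' @export
weights_matrix <- function(weights) {
  G <- matrix(0, weights$n, weights$n)
  G[cbind(weights$tgt, weights$src)] <- weights$w
  G
}

# per-node product over incoming-edge factors, robust to nonpositive
# factors (log-domain magnitudes + sign parity)
edge_product <- function(fact, tgt, n) {
  out <- rep(1, n)
  if (length(fact) == 0L) return(out)
  zero <- fact == 0
  lg <- rowsum(ifelse(zero, 0, log(abs(fact))), tgt)
  ng <- rowsum(cbind(as.numeric(fact < 0), as.numeric(zero)), tgt)
  idx <- as.integer(rownames(lg))
  prod <- exp(lg[, 1L]) * (-1)^ng[, 1L]
  prod[ng[, 2L] > 0] <- 0
  out[idx] <- prod
  out
}

#' Effective gene activity under regulation
#'
#' The regulated component is the product `P_i = prod_j (1 + gamma_ij *
#' hill(c_j))` over the regulators j of gene i (empty product = 1).
#' Under the default additive form the activity is `g_i = g0 + P_i`
#' (basal activity plus regulated component); under the multiplicative
#' form it is `g_i = g0 * P_i`. Either way the result is clamped below
#' at `g_floor` to keep activities positive under strong repression.
#'
#' @param c nonnegative concentration vector.
#' @param weights an `interaction_weights` object.
#' @param params a [stability_params] object.
#' @return gene activity vector, bounded below by `g_floor`.
#' @export
gene_activity <- function(c, weights, params = stability_params()) {
  K <- resolve_K(params, weights$n)
  H <- hill(c, K, params$h)
  fact <- 1 + weights$w * H[weights$src]
  P <- edge_product(fact, weights$tgt, weights$n)
  g <- if (params$form == "additive") params$g0 + P else params$g0 * P
  pmax(g, params$g_floor)
}

#' Gene allocation fractions
#'
#' `phi_i = g_i / sum_k g_k`: the fraction of active RNA polymerase
#' allocated to gene i. Sums to 1.
#'
#' @inheritParams gene_activity
#' @return probability vector over genes.
#' @export
allocation_fractions <- function(c, weights, params = stability_params()) {
  g <- gene_activity(c, weights, params)
  g / sum(g)
}

#' Solve for the steady-state concentration vector
#'
#' Damped fixed-point iteration `c <- (1 - d) c + d phi(c)` from the
#' uniform start `c = 1/N` until the maximal change falls below `fp_tol`.
#' The multiplicative rate `k_p c_r` of the concentration dynamics does
#' not move the fixed point and is not needed for the stability metric.
#'
#' @param weights an `interaction_weights` object.
#' @param params a [stability_params] object.
#' @return list with `c_star` (fixed point, sums to 1) and `converged`.
#' @export
solve_steady_state <- function(weights, params = stability_params()) {
  n <- weights$n
  c <- rep(1 / n, n)
  d <- params$damping
  converged <- FALSE
  for (it in seq_len(params$fp_max_iter)) {
    phi <- allocation_fractions(c, weights, params)
    cn <- (1 - d) * c + d * phi
    if (max(abs(cn - c)) < params$fp_tol) {
      c <- cn
      converged <- TRUE
      break
    }
    c <- cn
  }
  list(c_star = c, converged = converged)
}

#' Gene-gene Jacobian of the allocation fractions
#'
#' Computes `M_ij = d phi_i / d c_j` analytically at the fixed point:
#' `d g_i / d c_j = g_i * gamma_ij * hill'(c_j) / (1 + gamma_ij *
#' hill(c_j))` for each regulator j (zero where the positivity clamp is
#' active), then `d phi_i / d c_j = (d g_i / d c_j) / G - g_i *
#' (sum_k d g_k / d c_j) / G^2` with `G = sum g`. Columns of `M` sum to
#' zero because the phi vector sums to a constant.
#'
#' @param weights an `interaction_weights` object.
#' @param c_star steady-state concentration vector.
#' @param params a [stability_params] object.
#' @return the `N x N` Jacobian matrix `M`.
#' @export
jacobian_M <- function(weights, c_star, params = stability_params()) {
  n <- weights$n
  K <- resolve_K(params, n)
  H <- hill(c_star, K, params$h)
  Hp <- hill_deriv(c_star, K, params$h)
  fact <- 1 + weights$w * H[weights$src]
  P <- edge_product(fact, weights$tgt, n)
  g_raw <- if (params$form == "additive") params$g0 + P else params$g0 * P
  clamped <- g_raw <= params$g_floor
  g <- pmax(g_raw, params$g_floor)
  G <- sum(g)

  # d g_i / d c_j = (dP_i/dc_j or g0 dP_i/dc_j), with
  # dP_i/dc_j = P_i * gamma_ij * hill'(c_j) / (1 + gamma_ij hill(c_j))
  scale <- if (params$form == "additive") 1 else params$g0
  dg <- matrix(0, n, n)
  ok <- !clamped[weights$tgt] & fact != 0
  if (any(ok)) {
    i <- weights$tgt[ok]
    j <- weights$src[ok]
    dg[cbind(i, j)] <- scale * P[i] * weights$w[ok] * Hp[j] / fact[ok]
  }
  s <- colSums(dg)
  dg / G - outer(g, s) / G^2
}

#' Maximal real part of a matrix spectrum
#'
#' The stability metric: the largest real part over all eigenvalues.
#' Imaginary parts are ignored, so oscillatory but non-growing modes
#' count as stable.
#'
#' @param M square matrix.
#' @return a single number.
#' @export
lambda_max <- function(M) {
  max(Re(eigen(M, only.values = TRUE)$values))
}

#' Full stability analysis of one network
#'
#' Draws `n_weight_reps` independent link-strength assignments, solves
#' each to steady state and computes `lambda_M`. Non-converged replicates
#' are excluded (and counted).
#'
#' @param net a `grn` object.
#' @param params a [stability_params] object.
#' @return data frame with one row per converged weight replicate:
#'   `weight_rep`, `lambda_max`, `stable`; attribute `n_nonconverged`.
#' @export
network_stability <- function(net, params = stability_params()) {
  stopifnot_grn(net)
  rows <- list()
  bad <- 0L
  for (r in seq_len(params$n_weight_reps)) {
    w <- assign_weights(net, params)
    ss <- solve_steady_state(w, params)
    if (!ss$converged) {
      bad <- bad + 1L
      next
    }
    M <- jacobian_M(w, ss$c_star, params)
    lm <- lambda_max(M)
    rows[[length(rows) + 1L]] <- data.frame(
      weight_rep = r, lambda_max = lm, stable = lm < 1)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(weight_rep = integer(0), lambda_max = numeric(0),
               stable = logical(0))
  attr(out, "n_nonconverged") <- bad
  out
}

#' Stability across network models and sizes
#'
#' For each generator and size, generates `n_graph_reps` networks and
#' runs [network_stability] on each, giving `n_graph_reps *
#' n_weight_reps` values of `lambda_M` per cell. Used to compare how
#' quickly different network topologies lose stability as they grow.
#'
#' @param generators named list of functions `function(n) -> grn`.
#' @param sizes integer vector of network sizes.
#' @param n_graph_reps graphs per model/size cell (default 10).
#' @param params a [stability_params] object.
#' @return data frame of class `stability_curve` with columns `model`,
#'   `size`, `replicate`, `weight_rep`, `lambda_max`, `stable`.
#' @export
stability_curve <- function(generators, sizes, n_graph_reps = 10,
                            params = stability_params()) {
  stopifnot(is.list(generators), !is.null(names(generators)))
  rows <- list()
  for (model in names(generators)) {
    for (sz in sizes) {
      for (rep in seq_len(n_graph_reps)) {
        net <- generators[[model]](sz)
        res <- network_stability(net, params)
        if (nrow(res)) {
          res$model <- model
          res$size <- sz
          res$replicate <- rep
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("model", "size", "replicate", "weight_rep",
                 "lambda_max", "stable")]
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' Summarise a stability curve
#'
#' @param object a `stability_curve` data frame.
#' @param ... unused.
#' @return data frame with mean `lambda_max` and normal-theory 95%
#'   confidence bounds per model and size.
#' @export
summary.stability_curve <- function(object, ...) {
  sp <- split(object$lambda_max, list(object$model, object$size), drop = TRUE)
  res <- do.call(rbind, lapply(names(sp), function(key) {
    v <- sp[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(model = paste(parts[-length(parts)], collapse = "."),
               size = as.numeric(parts[length(parts)]),
               mean_lambda = mean(v),
               ci_lo = mean(v) - 1.96 * se,
               ci_hi = mean(v) + 1.96 * se,
               n = length(v))
  }))
  res[order(res$model, res$size), ]
}
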