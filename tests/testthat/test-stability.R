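test_that("hill function matches its closed form", {
  expect_equal(hill(0, K = 0.5, h = 2), 0)
  expect_equal(hill(0.5, K = 0.5, h = 2), 0.5)
  cs <- seq(0, 10, by = 0.1)
  vals <- hill(cs, K = 0.7, h = 3)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals < 1))
  expect_gt(hill(1e3, K = 0.7, h = 3), 0.999)
  expect_error(hill(-1, K = 0.5, h = 2), "negative")
})

test_that("weight assignment respects bounds and the half/half sign split", {
  net <- rand_g(20, 0.5)  # 10 edges
  sp <- stability_params()
  set.seed(61)
  w <- assign_weights(net, sp)
  expect_true(all(abs(w$w) <= 1.5))
  expect_true(all(w$w != 0))
  expect_equal(sum(w$w > 0), 5)
  expect_equal(sum(w$w < 0), 5)

  # odd edge count: one extra positive
  net2 <- grn(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  w2 <- assign_weights(net2, sp)
  expect_equal(sum(w2$w > 0) - sum(w2$w < 0), 1)

  # magnitudes follow the truncated normal
  set.seed(62)
  big <- rand_g(120, 50)
  wb <- assign_weights(big, sp)
  ptrunc <- function(q) {
    (pnorm(q, 0, sp$gamma_sd) - 0.5) / (pnorm(sp$gamma_bound, 0, sp$gamma_sd) - 0.5)
  }
  ks <- suppressWarnings(ks.test(abs(wb$w), ptrunc))
  expect_gt(ks$p.value, 0.001)

  expect_error(assign_weights(grn(rbind(c("a", "b"))), sp), "2 edges")
})

test_that("gene activity follows the regulation product in both forms", {
  net <- grn(rbind(c("a", "b"), c("a", "c")))
  spm <- stability_params(K = 0.5, form = "multiplicative")
  spa <- stability_params(K = 0.5, form = "additive")
  w <- assign_weights(net, spm)

  # unregulated gene sits at the basal level
  gm <- gene_activity(c(0, 0, 0), w, spm)
  expect_equal(gm[1], spm$g0)      # g0 * empty product
  ga <- gene_activity(c(0, 0, 0), w, spa)
  expect_equal(ga[1], spa$g0 + 1)  # g0 + empty product

  # single activator at saturation: g = 2.5 * g0 (multiplicative)
  w$w <- c(1.5, 1.5)
  g_sat <- gene_activity(c(1e6, 0, 0), w, spm)
  expect_equal(g_sat[2], 2.5 * spm$g0, tolerance = 1e-6)

  # zero-strength regulation: basal everywhere
  w$w <- c(0, 0)  # not produced by assign_weights, but valid input
  expect_equal(gene_activity(c(1, 2, 3), w, spm), rep(spm$g0, 3))
})

test_that("allocation fractions normalise and match a worked 3-node case", {
  net <- grn(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  sp <- stability_params(K = 0.5, h = 2, form = "multiplicative")
  set.seed(63)
  w <- assign_weights(net, sp)
  c0 <- c(0.3, 0.4, 0.3)
  phi <- allocation_fractions(c0, w, sp)
  expect_equal(sum(phi), 1)

  # hand recomputation through the defining equations
  G <- weights_matrix(w)
  f <- hill(c0, 0.5, 2)
  g_hand <- sapply(1:3, function(i) {
    fac <- 1 + G[i, ] * f
    fac[G[i, ] == 0] <- 1
    sp$g0 * prod(fac)
  })
  g_hand <- pmax(g_hand, sp$g_floor)
  expect_equal(phi, g_hand / sum(g_hand))

  # gamma = 0 gives the uniform allocation
  w0 <- w
  w0$w <- rep(0, length(w0$w))
  expect_equal(allocation_fractions(c0, w0, sp), rep(1 / 3, 3))
})

test_that("the fixed point solves c = phi(c) independent of damping", {
  set.seed(64)
  net <- rand_g(5, 1.6)
  sp <- stability_params()
  w <- assign_weights(net, sp)
  ss <- solve_steady_state(w, sp)
  expect_true(ss$converged)
  expect_equal(sum(ss$c_star), 1, tolerance = 1e-8)
  phi <- allocation_fractions(ss$c_star, w, sp)
  expect_lt(max(abs(ss$c_star - phi)), sp$fp_tol * 10)

  sp2 <- stability_params(damping = 0.3)
  ss2 <- solve_steady_state(w, sp2)
  expect_lt(max(abs(ss$c_star - ss2$c_star)), 10 * sp$fp_tol * 100)

  # gamma = 0: uniform fixed point immediately
  w0 <- w
  w0$w <- rep(0, length(w0$w))
  ss0 <- solve_steady_state(w0, sp)
  expect_equal(ss0$c_star, rep(1 / 5, 5))
})

test_that("the analytic Jacobian matches finite differences and sums to zero", {
  set.seed(65)
  for (rep in 1:4) {
    net <- rand_g(6, 2)
    sp <- stability_params(form = if (rep %% 2) "additive" else "multiplicative")
    w <- assign_weights(net, sp)
    ss <- solve_steady_state(w, sp)
    expect_true(ss$converged)
    M <- jacobian_M(w, ss$c_star, sp)

    expect_lt(max(abs(colSums(M))), 1e-10)

    eps <- 1e-6
    M_num <- matrix(0, 6, 6)
    for (j in 1:6) {
      up <- ss$c_star; up[j] <- up[j] + eps
      dn <- ss$c_star; dn[j] <- dn[j] - eps
      M_num[, j] <- (allocation_fractions(up, w, sp) -
                     allocation_fractions(dn, w, sp)) / (2 * eps)
    }
    expect_lt(max(abs(M - M_num)), 1e-6)
  }

  # gamma = 0 gives the zero Jacobian
  net <- rand_g(4, 1.5)
  sp <- stability_params()
  w <- assign_weights(net, sp)
  w$w <- rep(0, length(w$w))
  M0 <- jacobian_M(w, rep(0.25, 4), sp)
  expect_equal(M0, matrix(0, 4, 4))
})

test_that("lambda_max takes the maximal real part, ignoring oscillation", {
  expect_equal(lambda_max(matrix(0, 3, 3)), 0)
  expect_equal(lambda_max(diag(c(0.5, -2))), 0.5)
  expect_equal(lambda_max(rbind(c(0, -1), c(1, 0))), 0, tolerance = 1e-12)
})

test_that("weaker interactions give weakly smaller lambda_max", {
  set.seed(66)
  net <- rand_g(60, 2.5)
  sp <- stability_params()
  lam <- sapply(c(1, 0.5, 0.25), function(s) {
    vals <- replicate(5, {
      w <- assign_weights(net, sp)
      w$w <- w$w * s
      ss <- solve_steady_state(w, sp)
      lambda_max(jacobian_M(w, ss$c_star, sp))
    })
    mean(vals)
  })
  expect_true(all(diff(lam) < 0.02))  # decreasing up to noise
  expect_gt(lam[1], lam[3])
})

test_that("stability curves tabulate per-replicate lambda values", {
  set.seed(67)
  gens <- list(rg = function(n) rand_g(n, 2),
               dg = function(n) dag(n, 2))
  curve <- stability_curve(gens, sizes = c(30, 60), n_graph_reps = 2,
                           params = stability_params(n_weight_reps = 2))
  expect_s3_class(curve, "stability_curve")
  expect_equal(nrow(curve), 2 * 2 * 2 * 2)
  s <- summary(curve)
  expect_equal(nrow(s), 4)
  expect_true(all(s$ci_lo <= s$mean_lambda & s$mean_lambda <= s$ci_hi))
})
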