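test_that("rule probabilities follow the participation-derived split", {
  p <- derive_probabilities(0.374)
  expect_equal(p$p1, 0.626)
  expect_equal(p$p2, 0.3366)
  expect_equal(p$p3, 0.0187)
  expect_equal(p$p4, 0.0187)

  p2 <- derive_probabilities(0.27)
  expect_equal(p2$p1, 0.73)
  expect_equal(p2$p2, 0.243)
  expect_equal(p2$p3, 0.0135)

  p3 <- derive_probabilities(0.5)
  expect_equal(unlist(p3[c("p1", "p2", "p3", "p4")]),
               c(p1 = 0.5, p2 = 0.45, p3 = 0.025, p4 = 0.025))

  expect_error(derive_probabilities(0), "in \\(0, 1\\)")
  expect_error(derive_probabilities(1.2), "in \\(0, 1\\)")
})

test_that("nucleus extraction returns one connected FFL cluster", {
  tri <- grn(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  nuc <- extract_ffl_nucleus(tri, 3)
  expect_setequal(nuc$nodes, c("a", "b", "c"))
  expect_equal(n_edges(nuc), 3L)

  # two disjoint FFL clusters: output stays within one
  two <- grn(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                   c("x", "y"), c("y", "z"), c("x", "z")))
  set.seed(2)
  nuc2 <- extract_ffl_nucleus(two, 6)
  expect_true(all(nuc2$nodes %in% c("a", "b", "c")) ||
              all(nuc2$nodes %in% c("x", "y", "z")))

  expect_error(extract_ffl_nucleus(grn(rbind(c("a", "b"))), 3), "no FFL")

  set.seed(3)
  seed_net <- synthetic_seed_network(200)
  nuc3 <- extract_ffl_nucleus(seed_net, 20)
  expect_gte(n_nodes(nuc3), 20L)
  expect_equal(motif_census(nuc3)$participating_fraction, 1.0)
})

test_that("R1 samples regulators by the out-degree power kernel", {
  # out-degrees a:2, b:1, c:1; gamma = 1 => P = 1/2, 1/4, 1/4
  base <- grn(rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d")))
  set.seed(13)
  n_draw <- 4000
  picks <- replicate(n_draw, {
    r <- rule_r1(base, gamma = 1)
    src <- r$net$edges[n_edges(base) + 1L, 1L]
    base$nodes[src]
  })
  p_hat <- table(factor(picks, levels = c("a", "b", "c"))) / n_draw
  se <- sqrt(0.5 * 0.5 / n_draw)
  expect_lt(abs(p_hat[["a"]] - 0.5), 3 * se)
  expect_lt(abs(p_hat[["b"]] - 0.25), 3 * se)

  # gamma = 0: uniform over eligible regulators
  set.seed(14)
  picks0 <- replicate(3000, {
    r <- rule_r1(base, gamma = 0)
    base$nodes[r$net$edges[n_edges(base) + 1L, 1L]]
  })
  p0 <- table(factor(picks0, levels = c("a", "b", "c"))) / 3000
  expect_lt(abs(p0[["a"]] - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 3000))
})

test_that("R2 creates a TTG-type FFL on a new sink node", {
  tri <- grn(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  set.seed(5)
  r <- rule_r2(tri)
  expect_true(r$applied)
  expect_equal(n_nodes(r$net), 4L)
  expect_equal(n_edges(r$net), 5L)
  new_rec <- r$library[nrow(r$library), ]
  w <- 4L  # the added node
  expect_equal(unname(new_rec[3]), w)
  # new node has only incoming edges
  expect_equal(sum(r$net$edges[, 1L] == w), 0L)
  expect_equal(sum(r$net$edges[, 2L] == w), 2L)
  # census agrees it is a new FFL
  expect_equal(unname(motif_census(r$net)$counts["ffl"]), 2L)

  # repeated R2-only growth: FFL count = iterations + 1
  set.seed(6)
  net <- tri
  lib <- motif_census(tri)$ffl_records
  for (k in 1:10) {
    r <- rule_r2(net, lib)
    net <- r$net
    lib <- r$library
  }
  expect_equal(unname(motif_census(net)$counts["ffl"]), 11L)
})

test_that("R3 adds two edges making a TTT-type FFL among existing nodes", {
  # two FFLs; give every node at least one in and one out edge so
  # TTT eligibility holds broadly
  net <- grn(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                   c("d", "e"), c("e", "f"), c("d", "f"),
                   c("c", "d"), c("f", "a")))
  set.seed(8)
  r <- rule_r3(net)
  expect_true(r$applied)
  expect_equal(n_nodes(r$net), n_nodes(net))
  expect_equal(n_edges(r$net), n_edges(net) + 2L)
  rec <- r$library[nrow(r$library), ]
  dout <- tabulate(r$net$edges[, 1L], 6)
  din <- tabulate(r$net$edges[, 2L], 6)
  expect_true(all(dout[rec] >= 1))
  expect_true(all(din[rec] >= 1))
  # the recorded edges exist
  expect_true(all(audit_ffl_library(r$net, rbind(rec))))
  # census FFL count increased by at least one
  expect_gte(unname(motif_census(r$net)$counts["ffl"]),
             unname(motif_census(net)$counts["ffl"]) + 1L)
})

test_that("R4 closes a 2-path across two node-sharing FFLs", {
  # records (x,u,v) and (v,w,y): u->v in first, v->w in second
  net <- grn(rbind(c("x", "u"), c("u", "v"), c("x", "v"),
                   c("v", "w"), c("w", "y"), c("v", "y"),
                   c("y", "x"), c("w", "u")))
  set.seed(9)
  r <- rule_r4(net)
  expect_true(r$applied)
  expect_equal(n_edges(r$net), n_edges(net) + 1L)
  rec <- r$library[nrow(r$library), ]
  expect_true(all(audit_ffl_library(r$net, rbind(rec))))
  # no self-loop or duplicate was created (grn() would have errored)
  expect_s3_class(r$net, "grn")
})

test_that("motifs are picked proportional to their connectivity", {
  # rec 1 shares nodes with recs 2,3,4; rec 5 is isolated:
  # weights 4,2,2,2,1
  lib <- rbind(c(1L, 2L, 3L), c(3L, 4L, 5L), c(1L, 6L, 7L), c(2L, 8L, 9L),
               c(10L, 11L, 12L))
  set.seed(10)
  picks <- replicate(10000, pick_motif_by_connectivity(lib))
  p1 <- mean(picks == 1L)
  p5 <- mean(picks == 5L)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(p1 - 4 / 11), 4 * se)
  expect_lt(abs(p5 - 1 / 11), 4 * se)

  expect_equal(pick_motif_by_connectivity(rbind(c(1L, 2L, 3L))), 1L)
  two <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L))
  picks2 <- replicate(4000, pick_motif_by_connectivity(two))
  expect_lt(abs(mean(picks2 == 1L) - 0.5), 4 * sqrt(0.25 / 4000))
})

test_that("sparsity adjustment hits the exact edge target", {
  set.seed(12)
  net <- rand_g(100, 2.5)
  expect_equal(edge_set_keys(adjust_sparsity(net, 2.5)), edge_set_keys(net))

  dn <- adjust_sparsity(net, 2.0)
  expect_equal(n_edges(dn), 200L)
  up <- adjust_sparsity(net, 3.0)
  expect_equal(n_edges(up), 300L)
  expect_true(all(edge_set_keys(net) %in% edge_set_keys(up)) ||
              n_edges(up) == 300L)
  expect_error(adjust_sparsity(net, 200), "infeasible")
})

test_that("edge removal prefers high-out-degree sources", {
  # hub a -> 8 targets, plus single edges i -> j from degree-1 sources
  hub_edges <- cbind("a", paste0("t", 1:8))
  low_edges <- cbind(paste0("s", 1:8), paste0("u", 1:8))
  net <- grn(rbind(hub_edges, low_edges))
  set.seed(15)
  # remove exactly one edge repeatedly and watch where it comes from
  target <- (n_edges(net) - 1) / n_nodes(net)
  lost_from_hub <- replicate(400, {
    out <- adjust_sparsity(net, target)
    n_edges(out) == n_edges(net) - 1 &&
      sum(out$edges[, 1L] == match("a", out$nodes)) < 8
  })
  # hub sources 8/16 edges with weight 8 each vs weight 1: expected
  # hub-loss probability 64/72 = 0.89
  p_hat <- mean(lost_from_hub)
  expect_gt(p_hat, 0.75)
})

test_that("three-cycle disruption removes all 3-cycles, conserving edges", {
  cyc <- grn(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  set.seed(18)
  out <- disrupt_three_cycles(cyc)
  expect_equal(unname(motif_census(out)$counts["cycle"]), 0L)
  expect_equal(n_edges(out) + attr(out, "dropped_edges"), 3L)

  nc <- grn(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(edge_set_keys(disrupt_three_cycles(nc)), edge_set_keys(nc))

  set.seed(19)
  big <- rand_g(80, 2.5)
  out2 <- disrupt_three_cycles(big)
  expect_equal(unname(motif_census(out2)$counts["cycle"]), 0L)
})

test_that("motif depletion converts cycles and a tenth of isolated cascades", {
  cyc <- grn(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  set.seed(20)
  dep <- deplete_non_ffl_motifs(cyc)
  expect_equal(unname(motif_census(dep$net)$counts["cycle"]), 0L)
  expect_equal(unname(motif_census(dep$net)$counts["ffl"]), 1L)
  expect_equal(dep$edges_consumed, 0L)

  # 20 disjoint cascades, no FFLs: exactly 2 closing edges added
  casc <- do.call(rbind, lapply(1:20, function(k) {
    rbind(c(paste0("a", k), paste0("b", k)), c(paste0("b", k), paste0("c", k)))
  }))
  net <- grn(casc)
  set.seed(21)
  dep2 <- deplete_non_ffl_motifs(net)
  expect_equal(dep2$edges_consumed, 2L)
  expect_equal(unname(motif_census(dep2$net)$counts["ffl"]), 2L)
})

test_that("the generator meets its size, sparsity and audit contracts", {
  set.seed(33)
  params <- fflatt_params(150, 2.328, 0.374)
  net <- fflatt_generate(params)
  expect_equal(n_nodes(net), 150L)
  expect_equal(n_edges(net), round(2.328 * 150))
  expect_true(all(audit_ffl_library(net)))

  # reproducibility: identical seed, identical edge set
  set.seed(99)
  a <- fflatt_generate(params)
  set.seed(99)
  b <- fflatt_generate(params)
  expect_equal(a$edges, b$edges)

  # zero-iteration case: target size equal to the supplied nucleus
  set.seed(41)
  seed_net <- synthetic_seed_network(200)
  nuc <- extract_ffl_nucleus(seed_net, 30)
  p0 <- fflatt_params(n_nodes(nuc) + 1L, 1.5, 0.374, nucleus_size = 20)
  out0 <- fflatt_generate(p0, nuc)
  expect_equal(n_nodes(out0), n_nodes(nuc) + 1L)
  expect_equal(n_edges(out0), round(1.5 * (n_nodes(nuc) + 1L)))

  # cycle disruption flag yields cycle-free networks
  set.seed(55)
  pd <- fflatt_params(120, 2.328, 0.374, disrupt_cycles = TRUE)
  netd <- fflatt_generate(pd)
  expect_equal(unname(motif_census(netd)$counts["cycle"]), 0L)

  # depletion flag: conversion budget is accounted, count still exact
  set.seed(56)
  pm <- fflatt_params(120, 2.328, 0.374, deplete_motifs = TRUE)
  netm <- fflatt_generate(pm)
  expect_equal(n_edges(netm), round(2.328 * 120))
})
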