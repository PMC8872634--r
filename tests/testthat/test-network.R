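test_that("grn construction enforces simple-digraph invariants", {
  net <- grn(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 3L)

  expect_error(grn(rbind(c("a", "a"))), "self-loop")
  expect_error(grn(rbind(c("a", "b"), c("a", "b"))), "duplicate")
  expect_message(net2 <- grn(rbind(c("a", "b"), c("a", "b"), c("a", "a")),
                             collapse = TRUE))
  expect_equal(n_edges(net2), 1L)
})

test_that("edge-list files round-trip and report malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb", "a\tc", "b\tc"), f)
  net <- read_edge_list(f)
  expect_equal(n_edges(net), 3L)

  # duplicates collapsed, self-loops dropped, with messages
  writeLines(c("a\tb", "a\tb", "c\tc"), f)
  expect_message(net2 <- read_edge_list(f))
  expect_equal(n_edges(net2), 1L)

  writeLines(c("a\tb", "only_one_token"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_edge_list(f), "empty")

  set.seed(11)
  big <- rand_g(30, 100 / 30)
  write_edge_list(big, f)
  back <- read_edge_list(f)
  expect_setequal(paste(back$nodes[back$edges[, 1]], back$nodes[back$edges[, 2]]),
                  paste(big$nodes[big$edges[, 1]], big$nodes[big$edges[, 2]]))

  # an empty network writes a header-only file, which reads back as the
  # empty-network error
  empty <- grn(NULL, nodes = c("a", "b"))
  write_edge_list(empty, f)
  expect_match(readLines(f)[1], "^#")
  expect_error(read_edge_list(f), "empty")
})

test_that("adjacency conversion follows the columns-regulate-rows convention", {
  net <- grn(rbind(c("a", "b")))
  A <- to_adjacency(net)
  expect_equal(unname(A), rbind(c(0L, 0L), c(1L, 0L)))

  expect_warning(net2 <- from_adjacency(diag(3)), "diagonal")
  expect_equal(n_edges(net2), 0L)
  expect_error(from_adjacency(matrix(1:6, 2)), "square")
  expect_error(from_adjacency(matrix(2, 1, 1)), "binary")

  set.seed(7)
  r <- random_digraph(12, 0.2)
  expect_equal(edge_set_keys(from_adjacency(to_adjacency(r))),
               edge_set_keys(r))
})

test_that("degree summary matches hand counts and conserves edge totals", {
  tri <- grn(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  ds <- degree_summary(tri)
  expect_equal(ds$sparsity, 1.0)
  expect_equal(ds$mean_out_nonzero, 1.5)
  expect_equal(ds$mean_in_nonzero, 1.5)

  star <- grn(cbind("a", c("b", "c", "d", "e")))
  ds2 <- degree_summary(star)
  expect_equal(ds2$sparsity, 0.8)
  expect_equal(ds2$mean_out_nonzero, 4)
  expect_equal(ds2$mean_in_nonzero, 1)

  expect_error(degree_summary(grn(NULL, nodes = character(0))), "empty")

  set.seed(5)
  for (i in 1:5) {
    g <- random_digraph(50, 0.05)
    ds3 <- degree_summary(g)
    expect_equal(ds3$sparsity * ds3$n_nodes, ds3$n_edges)
    expect_equal(sum(as.integer(names(ds3$in_hist)) * ds3$in_hist),
                 ds3$n_edges)
    expect_equal(sum(as.integer(names(ds3$out_hist)) * ds3$out_hist),
                 ds3$n_edges)
  }
})

test_that("degree report separates scale-free from uniform random wiring", {
  set.seed(21)
  sf <- lapply(1:4, function(i) scale_free_directed(400, 2.328))
  rg <- lapply(1:4, function(i) rand_g(400, 2.328))
  star <- lapply(1:4, function(i) grn(cbind(1, 2:9)))

  expect_true(degree_distribution_report(sf)$scale_free_like)
  expect_false(degree_distribution_report(rg)$scale_free_like)
  expect_false(degree_distribution_report(star)$scale_free_like)
  expect_error(degree_distribution_report(grn(NULL, nodes = "a")), "isolated")
})
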