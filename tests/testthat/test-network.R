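two_cliques <- function(conf_in = 0.95, conf_between = NULL) {
  a <- c("A1", "A2", "A3", "A4")
  b <- c("B1", "B2", "B3", "B4")
  pairs <- function(v) t(combn(v, 2))
  e <- rbind(pairs(a), pairs(b))
  edges <- data.frame(node_a = e[, 1], node_b = e[, 2],
                      confidence = conf_in, stringsAsFactors = FALSE)
  if (!is.null(conf_between)) {
    edges <- rbind(edges, data.frame(node_a = "A1", node_b = "B1",
                                     confidence = conf_between))
  }
  edges
}

test_that("edge lists are canonicalised and validated", {
  e <- as_edge_list(data.frame(node_a = c("B", "C"), node_b = c("A", "A"),
                               confidence = c(0.8, 0.9)))
  expect_true(all(e$node_a <= e$node_b))
  expect_error(as_edge_list(data.frame(node_a = "A", node_b = "A",
                                       confidence = 0.5)), "self-loop")
  expect_error(as_edge_list(data.frame(node_a = "A", node_b = "B",
                                       confidence = 1.2)), "confidence")
})

test_that("confidence filtering is inclusive, idempotent and monotone", {
  edges <- data.frame(node_a = c("A", "A", "B"), node_b = c("B", "C", "C"),
                      confidence = c(0.65, 0.70, 0.95))
  kept <- filter_edges(edges, 0.7)
  expect_equal(nrow(kept), 2L)  # 0.70 retained at the boundary
  expect_identical(filter_edges(kept, 0.7), kept)
  expect_identical(filter_edges(edges, 0), edges)
  expect_error(filter_edges(edges, 1.01), "min_confidence")
  for (t1 in c(0.2, 0.5, 0.8)) {
    hi <- filter_edges(edges, t1 + 0.1)
    lo <- filter_edges(edges, t1)
    expect_true(all(paste(hi$node_a, hi$node_b) %in%
                      paste(lo$node_a, lo$node_b)))
  }
})

test_that("clustering recovers two disconnected cliques at k = 2", {
  cl <- cluster_nodes(two_cliques(), k = 2, seed = 1)
  a_ids <- unique(cl[paste0("A", 1:4)])
  b_ids <- unique(cl[paste0("B", 1:4)])
  expect_length(a_ids, 1L)
  expect_length(b_ids, 1L)
  expect_false(a_ids == b_ids)
  # weakly bridged cliques still separate
  cl2 <- cluster_nodes(two_cliques(conf_between = 0.4), k = 2, seed = 1)
  expect_length(unique(cl2[paste0("A", 1:4)]), 1L)
  expect_length(unique(cl2[paste0("B", 1:4)]), 1L)
})

test_that("clustering yields a full partition with the degenerate cases", {
  edges <- two_cliques(conf_between = 0.5)
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  for (k in c(1, 2, 3, length(nodes))) {
    cl <- cluster_nodes(edges, k = k, seed = 1)
    expect_setequal(names(cl), nodes)        # every node exactly once
    expect_true(all(cl %in% seq_len(k)))
    if (k == 1) expect_true(all(cl == 1L))
    if (k == length(nodes)) expect_equal(sort(unname(cl)), seq_along(nodes))
  }
  expect_error(cluster_nodes(edges, k = length(nodes) + 1), "exceeds")
  expect_error(cluster_nodes(edges, k = 0), "k must be")
  # deterministic at a fixed seed
  expect_identical(cluster_nodes(edges, k = 3, seed = 9),
                   cluster_nodes(edges, k = 3, seed = 9))
})

test_that("the per-node mean-confidence filter drops weak nodes", {
  edges <- rbind(two_cliques(0.95),
                 data.frame(node_a = "A1", node_b = "W", confidence = 0.2))
  cl <- cluster_nodes(edges, k = 2, seed = 1, min_node_confidence = 0.5)
  expect_false("W" %in% names(cl))
  expect_setequal(names(cl), c(paste0("A", 1:4), paste0("B", 1:4)))
})

test_that("edge list TSV reading validates its columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tconfidence", "P1\tP2\t0.9", "P3\tP1\t0.4"),
             path)
  e <- read_edge_list(path)
  expect_equal(nrow(e), 2L)
  expect_true(all(e$node_a <= e$node_b))
  writeLines(c("a\tb", "P1\tP2"), path)
  expect_error(read_edge_list(path), "columns")
})
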