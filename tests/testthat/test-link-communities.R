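triangle <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"))

test_that("edge similarity is the inclusive-neighbourhood Jaccard", {
  expect_equal(edge_similarity(triangle, c("a", "b"), c("a", "c")), 1.0)
  path <- data.frame(a = c("a", "b"), b = c("b", "c"))
  expect_equal(edge_similarity(path, c("a", "b"), c("b", "c")), 1 / 3)
  star <- data.frame(a = c("a", "a"), b = c("b", "c"))
  expect_equal(edge_similarity(star, c("a", "b"), c("a", "c")), 1 / 3)
  expect_error(edge_similarity(triangle, c("a", "b"), c("b", "a")), "itself")
  expect_error(edge_similarity(triangle, c("a", "b"), c("x", "y")),
               "exactly one endpoint")
})

test_that("partition density scores cliques at 1 and trees at 0", {
  expect_equal(partition_density(rep(1L, 3), triangle), 1.0)
  tree <- data.frame(a = c("a", "a", "a"), b = c("b", "c", "d"))
  expect_equal(partition_density(rep(1L, 3), tree), 0)
  two_tri <- data.frame(a = c("a", "a", "b", "x", "x", "y"),
                        b = c("b", "c", "c", "y", "z", "z"))
  expect_equal(partition_density(rep(1:2, each = 3), two_tri), 1.0)
})

test_that("link clustering cuts at the density maximum on known graphs", {
  # single triangle: one community of 3 edges, D = 1
  lc <- cluster_links(triangle)
  expect_length(lc$communities, 1)
  expect_equal(lc$partition_density, 1.0)
  # single edge: one community, D = 0
  lc1 <- cluster_links(data.frame(a = "a", b = "b"))
  expect_length(lc1$communities, 1)
  expect_equal(lc1$partition_density, 0)
  # two triangles joined by a bridge: triangles recovered, bridge separate
  g <- data.frame(a = c("a", "a", "b", "c", "x", "x", "y"),
                  b = c("b", "c", "c", "x", "y", "z", "z"))
  lc2 <- cluster_links(g)
  node_sets <- lapply(lc2$communities, `[[`, "nodes")
  expect_true(any(vapply(node_sets, identical, TRUE, y = c("a", "b", "c"))))
  expect_true(any(vapply(node_sets, identical, TRUE, y = c("x", "y", "z"))))
  expect_length(lc2$communities, 3)  # two triangles + the bridge edge
  expect_true(any(lc2$summary$small))
  expect_error(cluster_links(data.frame(a = character(0), b = character(0))),
               "empty graph")
})

test_that("edge partitions nest along the dendrogram", {
  set.seed(31)
  g <- random_edges(7, 11)
  lc <- cluster_links(g)
  hc <- lc$dendrogram
  hs <- sort(unique(c(0, hc$height)))
  prev <- stats::cutree(hc, h = hs[1])
  for (h in hs[-1]) {
    cur <- stats::cutree(hc, h = h)
    # refinement: edges together at a lower height stay together higher up
    expect_true(all(tapply(cur, prev, function(x) length(unique(x))) == 1))
    prev <- cur
  }
})

test_that("chosen cut attains the exhaustive-maximum partition density", {
  set.seed(41)
  for (rep in 1:25) {
    g <- random_edges(sample(4:7, 1), sample(2:12, 1))
    lc <- cluster_links(g)
    expect_equal(lc$partition_density, oracle_best_cut_density(lc$edges),
                 tolerance = 1e-12)
    # communities partition the edges and are edge-connected
    expect_equal(sum(vapply(lc$communities, function(cm) nrow(cm$edges), 0L)),
                 nrow(lc$edges))
    for (cm in lc$communities) {
      expect_true(oracle_density(rep(1, nrow(cm$edges)), cm$edges) >= 0)
      comp <- oracle_components(outer(seq_len(nrow(cm$edges)),
                                      seq_len(nrow(cm$edges)),
                                      Vectorize(function(i, j) {
        length(intersect(c(cm$edges$a[i], cm$edges$b[i]),
                         c(cm$edges$a[j], cm$edges$b[j]))) > 0
      })))
      expect_equal(length(unique(comp)), 1)  # connected edge subgraph
    }
  }
})

test_that("node overlap between communities is possible, edge overlap is not", {
  # bow-tie: two triangles sharing node c
  g <- data.frame(a = c("a", "a", "b", "c", "c", "d"),
                  b = c("b", "c", "c", "d", "e", "e"))
  lc <- cluster_links(g)
  all_edges <- do.call(rbind, lapply(lc$communities, `[[`, "edges"))
  expect_equal(nrow(unique(all_edges)), nrow(lc$edges))  # no edge reuse
  node_use <- table(unlist(lapply(lc$communities, `[[`, "nodes")))
  expect_true(max(node_use) >= 2)  # the shared node sits in both triangles
})
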