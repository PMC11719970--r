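test_that("knn_similarity_graph handles canonical fixtures", {
  # three identical rows, K = 1: with the deterministic (similarity desc,
  # id asc) tie-break every node picks the lowest-id other node, so the
  # union graph is the 2-edge star around s1 with unit weights and every
  # node has at least one incident edge
  X <- matrix(rep(c(0.2, 0.8, 0.5), each = 3), 3, 3,
              dimnames = list(paste0("s", 1:3), NULL))
  g <- knn_similarity_graph(X, 1)
  expect_identical(igraph::ecount(g), 2)
  expect_equal(igraph::E(g)$weight, rep(1, 2))
  expect_true(all(igraph::degree(g) >= 1))
  # orthogonal groups stay unconnected (zero similarities dropped)
  X2 <- rbind(matrix(rep(c(1, 0, 0, 0), each = 3), 3, 4),
              matrix(rep(c(0, 0, 1, 0), each = 3), 3, 4))
  rownames(X2) <- paste0("s", 1:6)
  g2 <- knn_similarity_graph(X2, 2)
  el <- igraph::as_edgelist(g2)
  grp <- function(v) v %in% paste0("s", 1:3)
  expect_true(all(grp(el[, 1]) == grp(el[, 2])))
  # K = n - 1: complete graph minus non-positive edges
  set.seed(3)
  X3 <- matrix(runif(5 * 4), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  g3 <- knn_similarity_graph(X3, 4)
  expect_identical(igraph::ecount(g3), choose(5, 2))
  # zero-norm rows are rejected by name
  X4 <- X3; X4[2, ] <- 0
  expect_error(knn_similarity_graph(X4, 2), "s2")
  expect_error(knn_similarity_graph(X3, 5), "at least K \\+ 1")
})

test_that("louvain_partition splits the two-clique fixture and reports
           independently recomputed modularity", {
  g <- two_clique_graph()
  cl <- louvain_partition(g, seed = 1L)
  expect_identical(cl$n_communities, 2L)
  memb <- cl$membership
  expect_identical(length(unique(memb[paste0("n", 1:5)])), 1L)
  expect_identical(length(unique(memb[paste0("n", 6:10)])), 1L)
  expect_equal(cl$modularity,
               igraph::modularity(g, memb + 1, weights = igraph::E(g)$weight),
               tolerance = 1e-9)
  expect_identical(louvain_partition(g, seed = 1L)$membership, memb)
  # single clique collapses to one community
  k5 <- igraph::make_full_graph(5)
  igraph::E(k5)$weight <- 1
  igraph::V(k5)$name <- paste0("v", 1:5)
  expect_identical(louvain_partition(k5, seed = 1L)$n_communities, 1L)
  # edgeless graph: every node its own community, flagged
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- paste0("v", 1:3)
  cl0 <- louvain_partition(g0)
  expect_true(cl0$no_edges)
  expect_identical(cl0$n_communities, 3L)
})

test_that("graph_modularity agrees with igraph on random weighted graphs", {
  set.seed(23)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(12, 0.4)
    igraph::V(g)$name <- paste0("v", 1:12)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 2)
    memb <- sample(0:2, 12, TRUE)
    expect_equal(graph_modularity(g, memb),
                 igraph::modularity(g, memb + 1,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-9)
  }
})

test_that("k_scan finds plateaus and flags their absence", {
  # two direction-separated blobs -> stable count 2 (cosine similarity is
  # scale-invariant, so the blobs must differ in direction, not magnitude)
  set.seed(6)
  X <- rbind(matrix(rnorm(20 * 5, 0, 0.05), 20, 5) +
               rep(c(0.8, 0.8, 0.1, 0.1, 0.1), each = 20),
             matrix(rnorm(20 * 5, 0, 0.05), 20, 5) +
               rep(c(0.1, 0.1, 0.1, 0.8, 0.8), each = 20))
  X <- pmin(pmax(X, 0.01), 0.99)
  rownames(X) <- paste0("s", 1:40)
  ks <- k_scan(X, k_min = 1L, k_max = 15L, seed = 4L)
  expect_true(ks$stable)
  expect_identical(ks$stable_count, 2L)
  expect_gte(ari(ks$assignment$membership, rep(1:2, each = 20)), 0.99)
  # window longer than the scanned range can never stabilize
  ks2 <- k_scan(X, k_min = 2L, k_max = 4L, window = 10L, seed = 4L)
  expect_false(ks2$stable)
  expect_identical(ks2$stable_k, 4L)
  expect_error(k_scan(X, k_max = 40L), "below the sample count")
})

test_that("ari matches known values", {
  expect_equal(ari(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_lt(abs(ari(rep(1:2, 50), rep(1:2, each = 50))), 0.1)
})
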