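test_that("knn includes self and breaks distance ties by lower index", {
  # three equidistant colinear points; middle point ties between endpoints
  x <- matrix(c(0, 1, 2), ncol = 1)
  nb <- knnNeighbors(x, k = 2)
  expect_setequal(nb[2, ], c(2L, 1L))     # self + lower-index endpoint
  expect_identical(nb[1, 1], 1L)
  # k = 1: every set is just the cell itself
  nb1 <- knnNeighbors(x, k = 1)
  expect_identical(as.vector(nb1), 1:3)
  # duplicates are each other's nearest neighbors
  y <- matrix(c(0, 0, 5), ncol = 1)
  nb2 <- knnNeighbors(y, k = 2)
  expect_setequal(nb2[1, ], c(1L, 2L))
  expect_setequal(nb2[2, ], c(2L, 1L))
  expect_error(knnNeighbors(x, k = 3), "smaller")
})

test_that("SNN Jaccard weights follow set arithmetic and pruning", {
  # |N_1|=|N_2|=3 sharing 2, union 4 -> weight 0.5
  nb <- rbind(c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L, 1L), c(4L, 1L, 2L))
  g <- snnJaccard(nb, prune = 0)
  expect_equal(snnAdjacency(g)[1, 2], 0.5)
  # identical neighbor sets -> weight 1
  nbSame <- rbind(c(1L, 2L), c(1L, 2L))
  gSame <- snnJaccard(nbSame, prune = 0)
  expect_equal(snnAdjacency(gSame)[1, 2], 1)
  # disjoint sets -> no edge
  nbDisj <- rbind(c(1L, 2L), c(3L, 4L), c(1L, 2L), c(3L, 4L))
  gD <- snnJaccard(nbDisj, prune = 1 / 15)
  expect_equal(snnAdjacency(gD)[1, 2], 0)
  # graph is symmetric with no self-loops (class validity enforces both)
  expect_s4_class(g, "SnnGraph")
})

twoCliqueGraph <- function(w = 0.01) {
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1
  a[5:8, 5:8] <- 1
  diag(a) <- 0
  a[4, 5] <- a[5, 4] <- w
  as(a, "CsparseMatrix")
}

test_that("Louvain recovers two cliques joined by a weak edge", {
  a <- twoCliqueGraph(0.01)
  lab <- louvainCluster(a, resolution = 0.5, seed = 1L)
  expect_length(unique(lab), 2)
  expect_length(unique(lab[1:4]), 1)
  expect_length(unique(lab[5:8]), 1)
  # achieved Q equals the exhaustive-partition optimum
  expect_equal(attr(lab, "modularity"),
               bruteForceMaxModularity(a, 0.5), tolerance = 1e-12)
})

test_that("a single clique collapses to one cluster", {
  a <- matrix(1, 5, 5)
  diag(a) <- 0
  lab <- louvainCluster(as(a, "CsparseMatrix"), resolution = 0.5, seed = 2L)
  expect_identical(unique(lab), 0L)
})

test_that("Louvain attains the brute-force modularity optimum on small graphs", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    a <- matrix(0, n, n)
    idx <- which(upper.tri(a))
    on <- sample(idx, round(0.5 * length(idx)))
    a[on] <- runif(length(on), 0.1, 1)
    a <- a + t(a)
    gamma <- sample(c(0.5, 1), 1)
    lab <- louvainCluster(as(a, "CsparseMatrix"), resolution = gamma,
                          seed = rep)
    expect_equal(attr(lab, "modularity"),
                 bruteForceMaxModularity(a, gamma), tolerance = 1e-10)
  }
})

test_that("modularity is non-decreasing across passes and output deterministic", {
  cfg <- tinySimConfig(seed = 33L, nCells = 200L)
  sce <- logNormalize(simulateTissueCounts(cfg, "lung"))
  hvgs <- selectHvgVst(sce, 200)
  emb <- scaleAndPca(sce, hvgs, 10)
  g <- snnJaccard(knnNeighbors(emb, 15))
  l1 <- louvainCluster(g, 0.5, seed = 7L)
  l2 <- louvainCluster(g, 0.5, seed = 7L)
  expect_identical(as.integer(l1), as.integer(l2))
  expect_true(all(diff(attr(l1, "passModularity")) >= -1e-12))
  # labels contiguous from 0, ordered by decreasing size
  sizes <- tabulate(l1 + 1L)
  expect_identical(sort(unique(l1)), seq_along(sizes) - 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("achieved modularity is no worse than igraph's Louvain", {
  skip_if_not_installed("igraph")
  a <- twoCliqueGraph(0.3)
  lab <- louvainCluster(a, resolution = 1, seed = 3L)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                            weighted = TRUE)
  set.seed(1)
  igLab <- igraph::membership(igraph::cluster_louvain(ig, resolution = 1))
  expect_gte(attr(lab, "modularity") + 1e-10,
             graphModularity(a, as.integer(igLab), 1))
})

test_that("planted well-separated populations are recovered exactly", {
  set.seed(44)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, mean = 0, sd = 0.3), n, 2),
             matrix(rnorm(n * 2, mean = 8, sd = 0.3), n, 2))
  g <- snnJaccard(knnNeighbors(x, 15))
  lab <- louvainCluster(g, 0.5, seed = 5L)
  expect_length(unique(lab), 2)
  expect_length(unique(lab[1:n]), 1)
  expect_length(unique(lab[(n + 1):(2 * n)]), 1)
})

test_that("the empty graph is rejected", {
  expect_error(louvainCluster(Matrix::sparseMatrix(i = integer(0),
                                                   j = integer(0),
                                                   dims = c(0, 0))),
               "empty")
})
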