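# LSI embedding, clustering, and the agreement / informativeness metrics.

test_that("LSI separates two perfectly distinct cell groups", {
  M <- Matrix::Matrix(rbind(c(5, 4, 0, 0),
                            c(4, 5, 0, 0),
                            c(0, 0, 5, 4),
                            c(0, 0, 4, 5)), sparse = TRUE,
                      dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:4)))
  emb <- lsi_embed(M, n_components = 2, drop_first = TRUE)
  s <- sign(emb[, 1])
  expect_true(all(s[1:2] == s[1]) && all(s[3:4] == s[3]) && s[1] != s[3])
})

test_that("LSI on a rank-1 matrix reconstructs with one component", {
  u <- c(1, 2, 3); v <- c(2, 1, 4, 1)
  M <- outer(u, v)
  emb <- lsi_embed(M, n_components = 1, drop_first = FALSE)
  # TF-IDF of a rank-1 non-negative matrix is still rank 1: the single
  # component carries the whole spectrum
  cs <- colSums(M)
  tf <- sweep(M, 2, cs, "/")
  idf <- log(1 + ncol(M) / rowSums(M > 0))
  X <- tf * idf
  expect_equal(sum(svd(X)$d[-1]), 0, tolerance = 1e-12)
  expect_equal(abs(as.numeric(emb)), svd(X)$d[1] * abs(svd(X)$v[, 1]),
               tolerance = 1e-10)
})

test_that("duplicating every cell preserves relative embedding geometry", {
  set.seed(7)
  M <- matrix(rpois(60, 2), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:10)))
  M2 <- cbind(M, M)
  colnames(M2) <- sprintf("c%d", 1:20)
  e1 <- lsi_embed(M, n_components = 3, drop_first = FALSE)
  e2 <- lsi_embed(M2, n_components = 3, drop_first = FALSE)
  d1 <- as.matrix(dist(e1))
  d2 <- as.matrix(dist(e2[1:10, ]))
  ratio <- d2[d1 > 1e-8] / d1[d1 > 1e-8]
  expect_lt(diff(range(ratio)), 1e-6)   # distances preserved up to one scale
})

test_that("LSI rejects degenerate input", {
  expect_error(lsi_embed(matrix(0, 3, 3)), "all-zero")
  expect_error(lsi_embed(matrix(1, 5, 5), n_components = 5), "n_components")
})

test_that("k-means recovers well-separated blobs deterministically", {
  set.seed(42)
  emb <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  rownames(emb) <- sprintf("c%d", 1:40)
  cl <- cluster_cells(emb, "kmeans", param = 2, seed = 3)
  truth <- rep(0:1, each = 20)
  expect_equal(ari(cl, truth), 1)
  expect_identical(cl, cluster_cells(emb, "kmeans", param = 2, seed = 3))
  expect_identical(sort(unique(cl)), 0:1)
  expect_error(cluster_cells(emb, "kmeans", param = 50, seed = 1), "exceeds")
  cl_leiden <- cluster_cells(emb, "leiden", param = 0.1, seed = 3, knn = 10)
  expect_equal(ari(cl_leiden, truth), 1)
  expect_identical(cl_leiden,
                   cluster_cells(emb, "leiden", param = 0.1, seed = 3, knn = 10))
})

test_that("ARI matches hand cases, the pair-count oracle, and mclust", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)      # relabel-invariant
  # all-ones 2x2 contingency: the adjustment formula gives -0.5
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  for (seed in 1:10) {
    set.seed(seed)
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:3, 30, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari_paircount(a, b), tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
  }
})

test_that("AMI matches reference values and limit cases", {
  expect_equal(ami(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ami(c(2, 2, 5, 5), c(0, 0, 1, 1)), 1)      # relabel-invariant
  expect_equal(ami(c(0, 0, 1, 1), c(0, 0, 0, 0)), 0)      # zero-MI case
  # reference values computed independently with scikit-learn
  expect_equal(ami(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5, tolerance = 1e-10)
  expect_equal(ami(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 1, 2)),
               0.5023607027202738, tolerance = 1e-9)
  expect_equal(ami(c(0, 0, 0, 1, 1, 2), c(1, 1, 0, 0, 2, 2)),
               0.08372678378671243, tolerance = 1e-9)
})

test_that("metrics reject partitions over different cell sets", {
  a <- setNames(c(0L, 0L, 1L), c("x", "y", "z"))
  b <- setNames(c(0L, 1L, 1L), c("x", "y", "w"))
  expect_error(ari(a, b), "different cells")
  expect_error(ami(a, b), "different cells")
})

test_that("Gini has its closed forms and scale invariance", {
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75)
  expect_equal(gini(c(0, 0, 0)), 0)
  for (seed in 1:10) {
    set.seed(seed)
    x <- rexp(sample(3:12, 1))
    expect_equal(gini(x), oracle_gini_pairs(x), tolerance = 1e-12)
    expect_equal(gini(7.3 * x), gini(x), tolerance = 1e-12)
  }
  expect_error(gini(c(-1, 2)), "non-negative")
  expect_error(gini(c(1, NA)), "finite")
})

test_that("RAGI contrasts marker and housekeeping cluster profiles", {
  cells <- sprintf("c%d", 1:8)
  cl <- setNames(rep(0:3, each = 2), cells)
  M <- rbind(marker = c(1, 1, 0, 0, 0, 0, 0, 0),     # only cluster 0
             hk = rep(1, 8))                         # uniform
  colnames(M) <- cells
  sets <- gene_set_pair("marker", "hk")
  r <- ragi(M, cl, sets)
  expect_equal(r$ragi, 0.75)    # gini(1,0,0,0) - gini(1,1,1,1)
  expect_equal(r$per_gene_gini$gini[r$per_gene_gini$gene == "marker"], 0.75)
  # same profiles in both sets -> zero difference
  M2 <- rbind(a = rep(1, 8), b = rep(1, 8))
  colnames(M2) <- cells
  expect_equal(ragi(M2, cl, gene_set_pair("a", "b"))$ragi, 0)
  expect_error(ragi(M, setNames(rep(0, 8), cells), sets), "2 clusters")
  expect_error(ragi(M[2, , drop = FALSE], cl, sets), "no marker genes")
  expect_warning(ragi(M, cl, gene_set_pair(c("marker", "ghost"), "hk")),
                 "absent")
})

test_that("differential activity ranks planted markers first", {
  set.seed(11)
  cells <- sprintf("c%d", 1:30)
  cl <- setNames(rep(0:2, each = 10), cells)
  M <- matrix(runif(5 * 30, 0, 0.05), 5, 30,
              dimnames = list(c("m0", "m1", "m2", "flat", "zero"), cells))
  for (k in 0:2) M[paste0("m", k), cl == k] <- 1
  M["flat", ] <- 0.5
  M["zero", ] <- 0
  da <- rank_differential_activity(M, cl, top_n = 2)
  for (k in 0:2)
    expect_identical(da$gene[da$cluster == k & da$rank == 1], paste0("m", k))
  expect_false(any(da$gene[da$rank == 1] %in% c("flat", "zero")))
})
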