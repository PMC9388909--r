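blobs <- function(centers, n_per, sd = 0.05, seed = 1) {
  set.seed(seed)
  M <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[k, ], each = n_per),
                 sd = sd), n_per)))
  rownames(M) <- sprintf("p%03d", seq_len(nrow(M)))
  attr(M, "truth") <- rep(seq_len(nrow(centers)), each = n_per)
  M
}

test_that("hierarchical clustering splits planted blobs and honours K", {
  M <- blobs(rbind(c(0, 0), c(10, 10)), n_per = 10)
  mod <- cluster_hierarchical(M, K = 2)
  expect_equal(adjusted_rand_index(mod$assignment, attr(M, "truth")), 1)
  modn <- cluster_hierarchical(M, K = nrow(M))
  expect_equal(length(unique(modn$assignment)), nrow(M))
  ## duplicated rows always co-cluster
  M2 <- rbind(M, M[1, , drop = FALSE])
  rownames(M2) <- c(rownames(M), "dup")
  m2 <- cluster_hierarchical(M2, K = 5)
  expect_equal(unname(m2$assignment["dup"]), unname(m2$assignment["p001"]))
})

test_that("k-means matches exhaustive partition optimum on a 1-D toy", {
  M <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "x"))
  mod <- cluster_kmeans(M, K = 2, seed = 3)
  expect_equal(unname(mod$assignment["a"]), unname(mod$assignment["b"]))
  expect_equal(unname(mod$assignment["c"]), unname(mod$assignment["d"]))
  expect_false(mod$assignment[["a"]] == mod$assignment[["c"]])
  ## K = 1: centroid is the column mean and WSS the total SS
  m1 <- cluster_kmeans(M, K = 1, seed = 3)
  expect_equal(unname(m1$params$centers[1, 1]), mean(M))
  expect_equal(m1$params$tot_withinss, sum((M - mean(M))^2))
})

test_that("GMM: likelihood ascends, blobs are recovered, mclust agrees", {
  M <- blobs(rbind(c(0, 0, 0), c(5, 5, 0), c(0, 5, 5)), n_per = 30, sd = 0.3,
             seed = 4)
  mod <- cluster_gmm(M, K_range = 2:5, n_init = 4, seed = 2)
  expect_equal(mod$K, 3)
  expect_equal(adjusted_rand_index(mod$assignment, attr(M, "truth")), 1)
  ## EM property: log-likelihood non-decreasing along the trace
  expect_true(all(diff(mod$params$ll_trace) > -1e-6))
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- Mclust(M, G = 2:5, verbose = FALSE)
  expect_equal(mod$K, mc$G)
  expect_equal(adjusted_rand_index(mod$assignment, mc$classification), 1)
})

test_that("BIC selects a single component for homogeneous Gaussian data", {
  wins <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    M <- matrix(rnorm(200 * 2), 200)
    rownames(M) <- sprintf("p%d", 1:200)
    mod <- cluster_gmm(M, K_range = 1:4, families = "EII", n_init = 2,
                       seed = s)
    if (mod$K == 1) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})

test_that("silhouette matches its definition and the brute-force oracle", {
  ## two far-apart tight pairs: closed form gives s close to 1
  M <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  rownames(M) <- letters[1:4]
  s <- silhouette_score(M, c(1, 1, 2, 2))
  expect_gt(s$mean, 0.95)
  ## all points identical: a = b = 0 -> s = 0
  M0 <- matrix(1, 4, 2, dimnames = list(letters[1:4], NULL))
  expect_equal(silhouette_score(M0, c(1, 1, 2, 2))$mean, 0)
  expect_error(silhouette_score(M, rep(1, 4)), "at least 2")
  set.seed(5)
  for (i in 1:5) {
    R <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("r%d", 1:10), NULL))
    cl <- sample(1:3, 10, replace = TRUE)
    if (length(unique(cl)) < 2) next
    expect_equal(unname(silhouette_score(R, cl)$widths), brute_silhouette(R, cl))
    if (requireNamespace("cluster", quietly = TRUE) && all(table(cl) > 1)) {
      ref <- cluster::silhouette(cl, dist(R))
      expect_equal(unname(silhouette_score(R, cl)$widths),
                   unname(ref[, "sil_width"]), tolerance = 1e-12)
    }
  }
})

test_that("model selection prefers the highest silhouette with gmm tie-break", {
  fake <- function(method, sil) structure(list(method = method, K = 2,
                                               silhouette = sil),
                                          class = "ptrans_cluster")
  models <- list(fake("hierarchical", 0.2), fake("kmeans", 0.5),
                 fake("gmm", 0.4))
  expect_identical(select_best_clustering(models)$method, "kmeans")
  expect_identical(select_best_clustering(models[1])$method, "hierarchical")
  tied <- list(fake("hierarchical", 0.5), fake("kmeans", 0.5), fake("gmm", 0.5))
  expect_identical(select_best_clustering(tied)$method, "gmm")
})

test_that("cluster summaries label behaviours and order canonically", {
  M <- rbind(matrix(rep(c(-1, 1, 1), each = 20), 20),
             matrix(rep(c(0, -1, 0), each = 15), 15),
             matrix(rep(c(0, 0, 0), each = 10), 10))
  M <- M + matrix(rnorm(length(M), sd = 0.01), nrow(M))
  colnames(M) <- c("mono", "light", "heavy")
  rownames(M) <- sprintf("g%02d", seq_len(nrow(M)))
  mod <- cluster_kmeans(M, K = 3, seed = 1)
  sm <- summarize_clusters(mod, M)
  expect_identical(sm$summary$label[1], "mono->polysomes shift")
  expect_identical(sm$summary$n, c(20L, 10L, 15L))
  expect_identical(sm$summary$label[sm$summary$n == 10L], "flat")
  expect_identical(sm$summary$label[sm$summary$n == 15L], "polysome depletion")
  expect_setequal(sm$gene_order, rownames(M))
  ## canonical ids follow the summary order
  expect_true(all(sm$assignment[rownames(M)[1:20]] == 1))
})

test_that("clustering is permutation-equivariant", {
  M <- blobs(rbind(c(0, 0), c(6, 0), c(0, 6)), n_per = 15, sd = 0.2, seed = 9)
  perm <- sample(nrow(M))
  Mp <- M[perm, ]
  for (fitter in list(
    function(x) cluster_hierarchical(x, 3)$assignment,
    function(x) cluster_kmeans(x, 3, seed = 7)$assignment,
    function(x) cluster_gmm(x, K_range = 3, families = "VVI", n_init = 3,
                            seed = 7)$assignment)) {
    a <- fitter(M); b <- fitter(Mp)
    expect_equal(adjusted_rand_index(a[rownames(M)], b[rownames(M)]), 1)
  }
})
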