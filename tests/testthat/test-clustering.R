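test_that("k = 1 returns the column means and total sum of squares", {
  set.seed(31)
  X <- matrix(rnorm(60), 20, 3)
  m <- kmeans_fit(X, 1, restarts = 3, seed = 1)
  expect_equal(m$centroids[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(m$wcss, sum(sweep(X, 2, colMeans(X))^2))
  expect_true(all(m$labels == 1L))
})

test_that("well-separated clouds are partitioned perfectly", {
  set.seed(32)
  X <- rbind(matrix(rnorm(40, -10, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2))
  truth <- rep(1:2, each = 20)
  m <- kmeans_fit(X, 2, restarts = 10, seed = 2)
  expect_equal(mclust::adjustedRandIndex(truth, m$labels), 1)
})

test_that("1-D six-point fixture reaches the enumerated optimum", {
  X <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  m <- kmeans_fit(X, 2, restarts = 10, seed = 3)
  expect_equal(m$wcss, 0.04, tolerance = 1e-12)
  expect_equal(m$wcss, brute_force_kmeans_wcss(X, 2), tolerance = 1e-12)
})

test_that("kept-best WCSS equals the exhaustive-partition minimum", {
  set.seed(33)
  for (case in 1:8) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    m <- kmeans_fit(X, k, restarts = 40, seed = case)
    expect_equal(m$wcss, brute_force_kmeans_wcss(X, k), tolerance = 1e-9,
                 label = sprintf("case %d (n=%d, k=%d)", case, n, k))
  }
})

test_that("model invariants: stored WCSS, surjective labels, determinism", {
  set.seed(34)
  X <- matrix(rnorm(120), 40, 3)
  m <- kmeans_fit(X, 4, restarts = 20, seed = 5)
  recomputed <- sum(vapply(seq_len(40), function(i)
    sum((X[i, ] - m$centroids[m$labels[i], ])^2), numeric(1)))
  expect_equal(m$wcss, recomputed, tolerance = 1e-10)
  expect_setequal(unique(m$labels), 1:4)
  expect_identical(m$labels, kmeans_fit(X, 4, restarts = 20, seed = 5)$labels)
  expect_error(kmeans_fit(X, 41, seed = 1), "k")
  expect_error(kmeans_fit(rbind(X, NA), 2, seed = 1), "missing")
})

test_that("kept-best WCSS agrees with an independent K-means", {
  set.seed(35)
  X <- rbind(matrix(rnorm(90, -2), 30, 3), matrix(rnorm(90, 2), 30, 3))
  m <- kmeans_fit(X, 3, restarts = 50, seed = 6)
  ref <- kmeans(X, 3, nstart = 50, iter.max = 100)
  expect_equal(m$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("Calinski-Harabasz matches the hand-computed four-point value", {
  # clusters {0, 0.1} and {10, 10.1}: WGSS = 0.01, BGSS = 100,
  # CH = (100 / 1) / (0.01 / 2) = 20000
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  ch <- validity_index(X, c(1, 1, 2, 2), "ch")
  expect_equal(as.numeric(ch), 20000, tolerance = 1e-9)
  expect_identical(attr(ch, "orientation"), "max")
})

test_that("silhouette agrees with the cluster package on random partitions", {
  set.seed(36)
  for (i in 1:6) {
    n <- sample(12:30, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(rep(seq_len(k), length.out = n))
    mine <- validity_index(X, lab, "silhouette")
    ref <- mean(cluster::silhouette(lab, dist(X))[, 3])
    expect_equal(as.numeric(mine), ref, tolerance = 1e-12)
  }
})

test_that("Davies-Bouldin matches a direct pairwise-formula evaluation", {
  set.seed(37)
  X <- matrix(rnorm(12), 6, 2)
  lab <- c(1, 1, 2, 2, 3, 3)
  cent <- rbind(colMeans(X[1:2, ]), colMeans(X[3:4, ]), colMeans(X[5:6, ]))
  S <- sapply(1:3, function(j)
    mean(sqrt(rowSums(sweep(X[lab == j, ], 2, cent[j, ])^2))))
  ratio <- function(i, j) (S[i] + S[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
  db_ref <- mean(sapply(1:3, function(i)
    max(sapply(setdiff(1:3, i), ratio, i = i))))
  expect_equal(as.numeric(validity_index(X, lab, "db")), db_ref,
               tolerance = 1e-12)
  # tighter clusters score lower under the minimize orientation
  expect_lt(validity_index(X * 0.01 + 10 * cbind(lab, lab), lab, "db"),
            validity_index(X + 10 * cbind(lab, lab), lab, "db"))
})

test_that("silhouette approaches 1 for vanishing within-cluster spread", {
  X <- matrix(c(0, 1e-9, 10, 10 + 1e-9), ncol = 1)
  expect_gt(validity_index(X, c(1, 1, 2, 2), "silhouette"), 0.999)
})

test_that("validity indices are invariant under cluster relabeling", {
  set.seed(38)
  X <- matrix(rnorm(60), 20, 3)
  lab <- sample(rep(1:3, length.out = 20))
  perm <- c(3L, 1L, 2L)
  relab <- perm[lab]
  for (idx in c("ch", "silhouette", "db", "dunn", "cindex", "ballhall"))
    expect_equal(as.numeric(validity_index(X, lab, idx)),
                 as.numeric(validity_index(X, relab, idx)),
                 tolerance = 1e-12, label = idx)
})

test_that("validity_index validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(validity_index(X, rep(1:2, 5), "nope"), "unknown")
  expect_error(validity_index(X, c(rep(1, 9), 3), "ch"), "surjective")
  expect_error(validity_index(X, rep(1:2, 5)[-1], "ch"), "match")
  expect_error(validity_index(X, rep(1:2, 5), "hartigan"), "sweep")
})

test_that("consensus recovers a planted three-blob structure", {
  wins <- vapply(1:20, function(s) {
    B <- make_blobs(s)
    consensus_k(B, k_range = 2:6, restarts = 10, seed = s,
                gap_B = 10)$winner
  }, integer(1))
  expect_gte(sum(wins == 3L), 18L)
})

test_that("consensus on structureless data still returns a full report", {
  set.seed(39)
  X <- matrix(rnorm(40 * 4), 40, 4)
  rep <- consensus_k(X, k_range = 2:5, restarts = 10, seed = 7, gap_B = 8)
  expect_true(rep$winner %in% 2:5)
  expect_length(rep$index_votes, 9L)
  expect_true(all(rep$index_votes %in% 2:5))
  expect_lte(rep$vote_count, 9L)
  expect_equal(rep$vote_fraction, rep$vote_count / 9)
  expect_equal(dim(rep$scores), c(9L, 4L))
})

test_that("consensus respects its k_range and validates the panel", {
  B <- make_blobs(1)
  expect_error(consensus_k(B, panel = character(0), seed = 1), "non-empty")
  expect_error(consensus_k(B, panel = "nope", seed = 1), "unknown")
  expect_error(consensus_k(B, k_range = 1:3, seed = 1), "k_range")
})

test_that("phenotype labels follow the centroid-mean ordering", {
  m <- structure(list(k = 3L, labels = c(1L, 2L, 3L),
                      centroids = rbind(c(0.5, 0.5), c(-0.3, -0.3),
                                        c(-1.1, -1.1)),
                      wcss = 0, restarts = 1L, seed = 1L),
                 class = "phenotype_model")
  lab <- label_phenotypes(m)
  expect_equal(unname(lab$cluster_labels),
               c("PC-like", "intermediate", "MI-like"))
  # tie on overall mean broken by the first coordinate (larger first)
  m$centroids <- rbind(c(1, -1), c(-1, 1), c(-2, -2))
  lab2 <- label_phenotypes(m)
  expect_equal(unname(lab2$cluster_labels),
               c("PC-like", "intermediate", "MI-like"))
  m$k <- 2L
  expect_error(label_phenotypes(m), "k = 3")
})

test_that("recovered labels agree with planted phenotypes above chance", {
  aris <- vapply(1:50, function(s) {
    co <- generate_cognitive_cohort(seed = s)
    m <- kmeans_fit(as.matrix(co[, cognitive_tests()]), 3,
                    restarts = 50, seed = s + 5000)
    mclust::adjustedRandIndex(co$planted_cluster, m$labels)
  }, numeric(1))
  expect_gte(mean(aris), 0.5)
  # fully separated planted clusters are recovered exactly
  tests <- cognitive_tests()
  specs <- lapply(1:3, function(i)
    cluster_spec(paste0("c", i), 15, setNames(rep(8 * i, 10), tests),
                 setNames(rep(0.3, 10), tests)))
  co <- generate_cognitive_cohort(specs, seed = 60)
  m <- kmeans_fit(as.matrix(co[, tests]), 3, restarts = 20, seed = 61)
  expect_equal(mclust::adjustedRandIndex(co$planted_cluster, m$labels), 1)
})
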