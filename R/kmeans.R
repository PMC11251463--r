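# squared Euclidean distances from every row of X to every row of C
dist2_to_centroids <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
}

# One Lloyd run from a random-subject initialization. Empty clusters are
# repaired by reseeding from the point farthest from its assigned centroid.
lloyd_once <- function(X, k, max_iter) {
  n <- nrow(X)
  C <- X[sample.int(n, k), , drop = FALSE]
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centroids(X, C)
    new_labels <- max.col(-d2, ties.method = "first")
    guard <- 0L
    repeat {  # reseed every empty cluster from the farthest point
      empty <- which(tabulate(new_labels, k) == 0L)
      guard <- guard + 1L
      if (!length(empty) || guard > 10L * k) break
      j <- empty[1L]
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      C[j, ] <- X[far, ]
      new_labels[far] <- j
      d2[far, j] <- 0
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) C[j, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  d2 <- dist2_to_centroids(X, C)
  wcss <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = C, wcss = wcss, iterations = iter)
}

#' K-means phenotype clustering with multiple restarts
#'
#' Lloyd's algorithm with random-subject initialization, repeated
#' `restarts` times; the partition with the smallest total within-cluster
#' sum of squares (WCSS) is kept. Restarting many times (default 50)
#' reduces the bias associated with the random selection of initial
#' centroids. Empty clusters arising during iteration are repaired by
#' reseeding the empty centroid at the point farthest from its current
#' centroid.
#'
#' @param data numeric matrix or data.frame, subjects x features (here:
#'   the 10 test z-scores); no missing values.
#' @param k number of clusters, `1 <= k < n`.
#' @param restarts number of random restarts (default 50).
#' @param seed integer seed; the kept solution is reproducible.
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return Object of class `phenotype_model`: `k`, `labels` (integer
#'   vector, values 1..k), `centroids` (k x p matrix), `wcss`, `restarts`,
#'   `seed`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40, -5), 20), matrix(rnorm(40, 5), 20))
#' m <- kmeans_fit(x, k = 2, restarts = 10, seed = 1)
#' m$wcss
kmeans_fit <- function(data, k, restarts = 50, seed, max_iter = 300) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("data must not contain missing values")
  n <- nrow(X)
  if (k < 1 || k >= n + (k == n)) stop("need 1 <= k <= n")
  if (k > n) stop("k must not exceed the number of subjects")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- if (k == 1L) {
        C <- matrix(colMeans(X), 1L, ncol(X), dimnames = list(NULL, colnames(X)))
        list(labels = rep(1L, n), centroids = C,
             wcss = sum(sweep(X, 2, C[1L, ])^2), iterations = 1L)
      } else lloyd_once(X, k, max_iter)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    colnames(best$centroids) <- colnames(X)
    structure(list(k = as.integer(k), labels = best$labels,
                   centroids = best$centroids, wcss = best$wcss,
                   restarts = as.integer(restarts), seed = as.integer(seed),
                   iterations = best$iterations),
              class = "phenotype_model")
  })
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("phenotype_model: k =", x$k, "| n =", length(x$labels),
      "| wcss =", format(x$wcss, digits = 6),
      "| restarts =", x$restarts, "\n")
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " / "), "\n")
  invisible(x)
}

#' Assign descriptive phenotype labels to a 3-cluster solution
#'
#' Orders the three clusters by the overall mean of their centroid entries:
#' the highest-scoring cluster is labeled `PC-like` (preserved cognition),
#' the lowest `MI-like` (multidomain involvement), the remaining one
#' `intermediate`. Ties in the overall mean are broken deterministically by
#' the centroid's first coordinate (larger first).
#'
#' @param model a [kmeans_fit()] result with `k = 3`.
#' @return Object of class `phenotype_labeling`: `cluster_labels` (named
#'   character vector, cluster id -> label) and `subject_labels`.
#' @export
label_phenotypes <- function(model) {
  stopifnot(inherits(model, "phenotype_model"))
  if (model$k != 3L) stop("phenotype labeling is defined for k = 3")
  overall <- rowMeans(model$centroids)
  ord <- order(-overall, -model$centroids[, 1L])
  cluster_labels <- character(3L)
  cluster_labels[ord] <- c("PC-like", "intermediate", "MI-like")
  names(cluster_labels) <- as.character(1:3)
  structure(list(cluster_labels = cluster_labels,
                 subject_labels = unname(cluster_labels[model$labels])),
            class = "phenotype_labeling")
}

#' @export
print.phenotype_labeling <- function(x, ...) {
  cat("phenotype_labeling:\n")
  print(x$cluster_labels)
  invisible(x)
}
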