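# ---- cluster-validity index panel -----------------------------------------
# Partition-level indices score one (data, labels) pair; sweep-level indices
# (Hartigan, Krzanowski-Lai, gap, Ball-Hall difference rule) need the WCSS
# curve across k and are evaluated inside consensus_k().

wcss_of <- function(X, labels, k = max(labels)) {
  s <- 0
  for (j in seq_len(k)) {
    pts <- X[labels == j, , drop = FALSE]
    if (nrow(pts)) s <- s + sum(sweep(pts, 2, colMeans(pts))^2)
  }
  s
}

index_ch <- function(X, labels) {
  n <- nrow(X); k <- max(labels)
  if (k < 2) return(NA_real_)
  gm <- colMeans(X)
  bgss <- 0
  for (j in seq_len(k)) {
    pts <- X[labels == j, , drop = FALSE]
    bgss <- bgss + nrow(pts) * sum((colMeans(pts) - gm)^2)
  }
  (bgss / (k - 1)) / (wcss_of(X, labels, k) / (n - k))
}

index_silhouette <- function(X, labels) {
  n <- nrow(X); k <- max(labels)
  if (k < 2) return(NA_real_)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sum(D[i, labels == own]) / (sizes[own] - 1L)
    b <- min(vapply(setdiff(seq_len(k), own),
                    function(j) mean(D[i, labels == j]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

index_db <- function(X, labels) {
  k <- max(labels)
  if (k < 2) return(NA_real_)
  cent <- t(vapply(seq_len(k), function(j)
    colMeans(X[labels == j, , drop = FALSE]), numeric(ncol(X))))
  S <- vapply(seq_len(k), function(j) {
    pts <- X[labels == j, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[j, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(cent))
  r <- vapply(seq_len(k), function(i)
    max(vapply(setdiff(seq_len(k), i),
               function(j) (S[i] + S[j]) / M[i, j], numeric(1))), numeric(1))
  mean(r)
}

index_dunn <- function(X, labels) {
  k <- max(labels)
  if (k < 2) return(NA_real_)
  D <- as.matrix(dist(X))
  sep <- Inf; diam <- 0
  for (i in seq_len(k)) {
    ii <- which(labels == i)
    if (length(ii) > 1L) diam <- max(diam, max(D[ii, ii]))
    for (j in seq_len(k)) if (j > i) {
      jj <- which(labels == j)
      sep <- min(sep, min(D[ii, jj, drop = FALSE]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

index_cindex <- function(X, labels) {
  k <- max(labels)
  if (k < 2) return(NA_real_)
  D <- as.matrix(dist(X))
  dvec <- D[upper.tri(D)]
  within <- outer(labels, labels, "==")[upper.tri(D)]
  nw <- sum(within)
  if (nw == 0) return(NA_real_)
  sw <- sum(dvec[within])
  sorted <- sort(dvec)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq.int(length(sorted) - nw + 1L, length(sorted))])
  if (smax == smin) return(0)
  (sw - smin) / (smax - smin)
}

index_ballhall <- function(X, labels) {
  wcss_of(X, labels) / max(labels)
}

#' Registry of cluster-validity indices
#'
#' The default consensus panel of nine indices. `orientation` states how
#' each index votes for the optimal k: `"max"` / `"min"` pick the extremal
#' score over the candidate range; `"diff"` (elbow) indices vote for the k
#' with the largest second difference of their level curve; `"gap"` applies
#' the
#' one-standard-error rule. `type` marks whether the score is a function of
#' one partition or of the whole WCSS-by-k sweep.
#'
#' @return `data.frame` with columns `name`, `orientation`, `type`.
#' @export
validity_indices <- function() {
  data.frame(
    name = c("ch", "silhouette", "db", "dunn", "cindex",
             "hartigan", "kl", "gap", "ballhall"),
    orientation = c("max", "max", "min", "max", "min",
                    "diff", "max", "gap", "diff"),
    type = c(rep("partition", 5L), "sweep", "sweep", "sweep", "sweep"),
    stringsAsFactors = FALSE
  )
}

#' Score one partition under a named cluster-validity index
#'
#' Computes the Calinski-Harabasz, mean silhouette, Davies-Bouldin, Dunn,
#' C-index, or Ball-Hall (WCSS/k) score of a clustering. Sweep-type indices
#' (Hartigan, Krzanowski-Lai, gap) depend on neighboring k and are
#' evaluated inside [consensus_k()].
#'
#' @param data subjects x features matrix.
#' @param labels integer cluster labels 1..k.
#' @param index_name one of the partition-level names in
#'   [validity_indices()].
#' @return Scalar score with attribute `orientation`.
#' @export
#' @examples
#' x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
#' validity_index(x, c(1, 1, 2, 2), "ch")
validity_index <- function(data, labels, index_name) {
  X <- as.matrix(data)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("labels must match data rows")
  if (!all(seq_len(max(labels)) %in% labels))
    stop("labels must be surjective onto 1..k")
  reg <- validity_indices()
  row <- reg[reg$name == index_name, ]
  if (nrow(row) == 0L) stop("unknown index: ", index_name)
  if (row$type == "sweep" && index_name != "ballhall")
    stop("index '", index_name,
         "' is defined on the WCSS-by-k sweep; use consensus_k()")
  fn <- switch(index_name,
               ch = index_ch, silhouette = index_silhouette, db = index_db,
               dunn = index_dunn, cindex = index_cindex,
               ballhall = index_ballhall)
  structure(fn(X, labels), orientation = row$orientation)
}
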