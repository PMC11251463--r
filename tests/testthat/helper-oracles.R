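# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and direct formula
# evaluation only.

# minimum WCSS over ALL assignments of n points to at most k clusters
brute_force_kmeans_wcss <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    w <- 0
    for (j in unique(labels)) {
      pts <- X[labels == j, , drop = FALSE]
      w <- w + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    if (w < best) best <- w
    # odometer increment over base-k label vectors
    i <- 1L
    while (i <= n && labels[i] == k) {
      labels[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    labels[i] <- labels[i] + 1L
  }
  best
}

# classical step-up BH: rejection set and adjusted p by direct enumeration
brute_force_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  rejected <- logical(m)
  if (kmax > 0L) rejected[ord[seq_len(kmax)]] <- TRUE
  adjusted <- numeric(m)
  for (i in seq_len(m))
    adjusted[ord[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  list(adjusted = adjusted, rejected = rejected)
}

# streamline-by-streamline disconnection recount (independent of the
# package's matrix bookkeeping)
brute_force_disconnection <- function(world, mask) {
  N <- max(world$parcellation)
  hit <- tot <- matrix(0, N, N)
  for (s in world$streamlines) {
    a <- min(s$a, s$b); b <- max(s$a, s$b)
    tot[a, b] <- tot[a, b] + 1
    if (length(intersect(s$voxels, mask))) hit[a, b] <- hit[a, b] + 1
  }
  out <- ifelse(tot > 0, hit / pmax(tot, 1), 0)
  out + t(out)
}

# three well-separated Gaussian blobs in 3-D
make_blobs <- function(seed, n_per = 20, sep = 6, sd = 0.5) {
  set.seed(seed)
  rbind(matrix(rnorm(3 * n_per, 0, sd), n_per, 3),
        matrix(rnorm(3 * n_per, sep, sd), n_per, 3),
        matrix(rnorm(3 * n_per, -sep, sd), n_per, 3))
}
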