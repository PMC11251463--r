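#' Consensus selection of the number of clusters by majority vote
#'
#' Fits K-means (via [kmeans_fit()], kept-best over `restarts`) for every
#' candidate k, scores each kept partition under a panel of cluster-validity
#' indices, lets each index vote for its optimal k according to its
#' orientation rule, and declares the modal k the winner (ties broken
#' toward the smaller k). All indices vote on the same kept-best K-means
#' partitions, so the voted k is the one the clustering itself will use.
#'
#' Orientation rules: `"max"`/`"min"` indices pick the extremal score over
#' `k_range`; `"diff"` (elbow) indices — Hartigan and Ball-Hall — vote for
#' the k with the largest second difference of their level curve (the point
#' of maximum curvature, `level(k-1) - 2 level(k) + level(k+1)`);
#' Krzanowski-Lai uses its
#' ratio of successive WCSS differences; the gap statistic uses the
#' one-standard-error rule against `gap_B` uniform reference datasets drawn
#' over the feature ranges.
#'
#' @param data subjects x features matrix (no missing values).
#' @param k_range candidate cluster numbers (default `2:8`).
#' @param panel character vector of index names from [validity_indices()]
#'   (default: all nine).
#' @param restarts K-means restarts per candidate k (default 50).
#' @param seed integer seed governing fits and gap references.
#' @param gap_B number of gap-statistic reference datasets (default 25).
#' @return Object of class `consensus_report`: `k_range`, `index_votes`
#'   (named integer vector), `winner`, `vote_count`, `vote_fraction`,
#'   `scores` (index x k matrix), and `fits` (the kept
#'   [kmeans_fit()] model per candidate k, named by k).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(60, -6), 30), matrix(rnorm(60, 6), 30))
#' rep <- consensus_k(x, k_range = 2:4, restarts = 10, seed = 1)
#' rep$winner
consensus_k <- function(data, k_range = 2:8,
                        panel = validity_indices()$name,
                        restarts = 50, seed, gap_B = 25) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(panel) == 0L) stop("panel must be non-empty")
  if (min(k_range) < 2 || max(k_range) >= n)
    stop("k_range must lie within (1, n)")
  unknown <- setdiff(panel, validity_indices()$name)
  if (length(unknown)) stop("unknown index: ", paste(unknown, collapse = ", "))

  lo <- min(k_range); hi <- max(k_range)
  k_all <- seq.int(max(1L, lo - 1L), min(n - 1L, hi + 1L))
  fits <- lapply(k_all, function(k)
    kmeans_fit(X, k, restarts = restarts,
               seed = substream_seed(seed, paste0("kmeans-k", k))))
  names(fits) <- as.character(k_all)
  W <- vapply(fits, function(f) f$wcss, numeric(1))

  part_scores <- function(fn) vapply(as.character(k_range), function(kc)
    fn(X, fits[[kc]]$labels), numeric(1))

  scores <- matrix(NA_real_, nrow = length(panel), ncol = length(k_range),
                   dimnames = list(panel, as.character(k_range)))
  votes <- setNames(integer(length(panel)), panel)
  kref <- as.character(k_range)

  vote_extremum <- function(sc, maximize) {
    sc[!is.finite(sc)] <- if (maximize) -Inf else Inf
    k_range[if (maximize) which.max(sc) else which.min(sc)]
  }
  # elbow: largest second difference of the level curve,
  # level(k-1) - 2*level(k) + level(k+1) (maximum curvature)
  vote_diff <- function(level) {
    curv <- vapply(k_range, function(k) {
      l0 <- level[as.character(k - 1L)]
      l1 <- level[as.character(k)]
      l2 <- level[as.character(k + 1L)]
      if (anyNA(c(l0, l1, l2))) NA_real_ else l0 - 2 * l1 + l2
    }, numeric(1))
    curv[!is.finite(curv)] <- -Inf
    k_range[which.max(curv)]
  }

  gap_stats <- NULL
  if ("gap" %in% panel) {
    rng_lo <- apply(X, 2, min); rng_hi <- apply(X, 2, max)
    k_gap <- seq.int(lo, min(n - 1L, hi + 1L))
    logWstar <- matrix(NA_real_, gap_B, length(k_gap),
                       dimnames = list(NULL, as.character(k_gap)))
    for (b in seq_len(gap_B)) {
      ref <- with_seed(substream_seed(seed, paste0("gap-ref", b)), {
        matrix(runif(n * p, rep(rng_lo, each = n), rep(rng_hi, each = n)), n, p)
      })
      for (k in k_gap) {
        f <- kmeans_fit(ref, k, restarts = 5,
                        seed = substream_seed(seed, paste0("gap-fit", b, "-", k)))
        logWstar[b, as.character(k)] <- log(f$wcss)
      }
    }
    gap <- colMeans(logWstar) - log(W[as.character(k_gap)])
    sk <- apply(logWstar, 2, sd) * sqrt(1 + 1 / gap_B)
    gap_stats <- list(gap = gap, sk = sk, k_gap = k_gap)
  }

  for (idx in panel) {
    ori <- validity_indices()$orientation[validity_indices()$name == idx]
    if (idx %in% c("ch", "silhouette", "db", "dunn", "cindex")) {
      fn <- switch(idx, ch = index_ch, silhouette = index_silhouette,
                   db = index_db, dunn = index_dunn, cindex = index_cindex)
      sc <- part_scores(fn)
      scores[idx, ] <- sc
      votes[idx] <- vote_extremum(sc, maximize = ori == "max")
    } else if (idx == "ballhall") {
      level <- W / as.numeric(names(W))
      scores[idx, ] <- level[kref]
      votes[idx] <- vote_diff(level)
    } else if (idx == "hartigan") {
      ks <- as.integer(names(W))
      H <- setNames(rep(NA_real_, length(W)), names(W))
      for (i in seq_along(ks)) {
        knext <- as.character(ks[i] + 1L)
        if (knext %in% names(W))
          H[i] <- (W[i] / W[knext] - 1) * (n - ks[i] - 1)
      }
      scores[idx, ] <- H[kref]
      votes[idx] <- vote_diff(H)
    } else if (idx == "kl") {
      ks <- as.integer(names(W))
      DIFF <- setNames(rep(NA_real_, length(W)), names(W))
      for (i in seq_along(ks)) {
        kprev <- as.character(ks[i] - 1L)
        if (kprev %in% names(W))
          DIFF[i] <- (ks[i] - 1)^(2 / p) * W[kprev] - ks[i]^(2 / p) * W[i]
      }
      kl <- vapply(k_range, function(k) {
        dk <- DIFF[as.character(k)]; dk1 <- DIFF[as.character(k + 1L)]
        if (is.na(dk) || is.na(dk1) || dk1 == 0) NA_real_ else abs(dk) / abs(dk1)
      }, numeric(1))
      scores[idx, ] <- kl
      votes[idx] <- vote_extremum(kl, maximize = TRUE)
    } else if (idx == "gap") {
      g <- gap_stats$gap; sk <- gap_stats$sk
      scores[idx, ] <- g[kref]
      pick <- NA_integer_
      for (k in k_range) {
        k1 <- as.character(k + 1L)
        if (k1 %in% names(g) && g[as.character(k)] >= g[k1] - sk[k1]) {
          pick <- k; break
        }
      }
      if (is.na(pick)) pick <- k_range[which.max(g[kref])]
      votes[idx] <- pick
    }
  }

  tab <- table(factor(votes, levels = k_range))
  winner <- as.integer(names(tab)[which.max(tab)])  # ties -> smaller k
  structure(list(k_range = k_range, index_votes = votes, winner = winner,
                 vote_count = as.integer(max(tab)),
                 vote_fraction = max(tab) / length(panel),
                 scores = scores,
                 fits = fits[as.character(k_range)]),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("consensus_report: winner k =", x$winner, sprintf(
    "(%d of %d indices, %.0f%%)\n", x$vote_count, length(x$index_votes),
    100 * x$vote_fraction))
  print(x$index_votes)
  invisible(x)
}
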