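#' Generate a toy voxel world: parcellation, streamlines, lesion masks
#'
#' Builds a small 3-D voxel grid containing `n_regions` cortical regions
#' (2 x 2 x 1 voxel blocks laid out on one slice) surrounded by white-matter
#' voxels, a reference streamline set connecting region pairs through the
#' white matter, a region-to-network labeling over the seven cortical
#' networks, and per-subject lesion masks drawn uniformly over white-matter
#' voxels. It stands in, at desk scale, for a reference tractogram plus
#' parcellation: the disconnection scoring contract is identical.
#'
#' @param n_regions number of regions (>= 2); default 20.
#' @param streamlines_per_pair streamlines between each connected pair.
#' @param lesion_fraction fraction of white-matter voxels lesioned per
#'   subject, in [0, 1].
#' @param n_subjects number of lesion masks to draw.
#' @param pair_density fraction of region pairs that are connected
#'   (default 1: all pairs); unconnected pairs score 0 and are flagged.
#' @param seed integer seed.
#' @return An object of class `toy_world`: `grid_shape`, `parcellation`
#'   (integer array, 0 = white matter / background), `network_labels`
#'   (region -> network name), `streamlines` (list of
#'   `list(a, b, voxels)` with 1-based linear voxel indices),
#'   `wm_voxels`, and `lesion_masks` (list of voxel-index vectors).
#' @export
#' @examples
#' w <- generate_toy_world(n_regions = 6, streamlines_per_pair = 3,
#'                         lesion_fraction = 0.1, seed = 7)
#' length(w$streamlines)
generate_toy_world <- function(n_regions = 20, streamlines_per_pair = 5,
                               lesion_fraction = 0.1, n_subjects = 1,
                               pair_density = 1, seed) {
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (lesion_fraction < 0 || lesion_fraction > 1)
    stop("lesion_fraction must lie in [0, 1]")
  cols <- ceiling(sqrt(n_regions))
  rows <- ceiling(n_regions / cols)
  grid_shape <- c(3L * cols + 1L, 3L * rows + 1L, 4L)
  parc <- array(0L, dim = grid_shape)
  for (r in seq_len(n_regions)) {
    i <- (r - 1L) %% cols
    j <- (r - 1L) %/% cols
    parc[(3L * i + 2L):(3L * i + 3L), (3L * j + 2L):(3L * j + 3L), 1L] <- r
  }
  region_voxels <- lapply(seq_len(n_regions), function(r) which(parc == r))
  wm <- which(parc == 0L)
  nets <- yeo7_networks()
  network_labels <- setNames(nets[((seq_len(n_regions) - 1L) %% 7L) + 1L],
                             as.character(seq_len(n_regions)))
  with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
    if (pair_density < 1) {
      keep <- runif(nrow(pairs)) < pair_density
      pairs <- pairs[keep, , drop = FALSE]
    }
    streamlines <- vector("list", nrow(pairs) * streamlines_per_pair)
    s <- 0L
    for (pr in seq_len(nrow(pairs))) {
      a <- as.integer(pairs[pr, 1L]); b <- as.integer(pairs[pr, 2L])
      for (k in seq_len(streamlines_per_pair)) {
        s <- s + 1L
        len <- sample(3:6, 1L)
        streamlines[[s]] <- list(
          a = a, b = b,
          voxels = c(sample(region_voxels[[a]], 1L),
                     sample(wm, len, replace = TRUE),
                     sample(region_voxels[[b]], 1L)))
      }
    }
    lesion_masks <- lapply(seq_len(n_subjects), function(i) {
      n_les <- round(lesion_fraction * length(wm))
      sort(sample(wm, n_les))
    })
    names(lesion_masks) <- sprintf("P%03d", seq_len(n_subjects))
    structure(list(grid_shape = grid_shape, parcellation = parc,
                   network_labels = network_labels,
                   streamlines = streamlines, wm_voxels = wm,
                   lesion_masks = lesion_masks),
              class = "toy_world")
  })
}

#' @export
print.toy_world <- function(x, ...) {
  cat("toy_world:", paste(x$grid_shape, collapse = " x "), "grid,",
      max(x$parcellation), "regions,", length(x$streamlines), "streamlines,",
      length(x$lesion_masks), "lesion mask(s)\n")
  invisible(x)
}

# 0-based (x, y, z) coordinates for linear voxel indices (used for JSON export)
voxel_xyz <- function(world, idx) {
  d <- world$grid_shape
  idx0 <- idx - 1L
  cbind(x = idx0 %% d[1L],
        y = (idx0 %/% d[1L]) %% d[2L],
        z = idx0 %/% (d[1L] * d[2L]))
}

#' Rank-1 factor covariance planted on one network's regions
#'
#' Builds the region-level covariance of a common-signal model: regions in
#' `members` share a latent factor with loading `loading`, so after adding
#' white noise of variance `noise_sd^2` (in [generate_bold()]) their
#' pairwise correlation is `loading^2 / (loading^2 + noise_sd^2)`.
#'
#' @param n_regions total region count.
#' @param members integer indices of the regions carrying the factor.
#' @param loading factor loading (default 1).
#' @return `n_regions` x `n_regions` positive-semidefinite matrix.
#' @export
factor_covariance <- function(n_regions, members, loading = 1) {
  lam <- rep(0, n_regions)
  lam[members] <- loading
  tcrossprod(lam)
}

#' Generate ROI-level BOLD time series with a planted covariance
#'
#' Draws `n_timepoints` independent multivariate-normal samples whose
#' zero-lag covariance is `planted_covariance + noise_sd^2 * I` — a
#' stationary white Gaussian process at the ROI level. Sampling interval
#' defaults to TR = 3 s.
#'
#' @param n_regions region count; must match `planted_covariance`.
#' @param planted_covariance symmetric positive-semidefinite matrix
#'   (default: all-zero, i.e. pure white noise).
#' @param n_timepoints series length (>= 64; default 128).
#' @param noise_sd white-noise SD added independently to every region.
#' @param tr_seconds sampling interval (> 0; default 3).
#' @param seed integer seed.
#' @return Object of class `bold_series`: `roi_ts` (region x timepoint
#'   matrix), `tr_seconds`, `planted_covariance`, `noise_sd`.
#' @export
generate_bold <- function(n_regions, planted_covariance = NULL,
                          n_timepoints = 128, noise_sd = 1,
                          tr_seconds = 3, seed) {
  if (is.null(planted_covariance))
    planted_covariance <- matrix(0, n_regions, n_regions)
  if (nrow(planted_covariance) != n_regions)
    stop("planted_covariance dimension must equal n_regions")
  if (max(abs(planted_covariance - t(planted_covariance))) > 1e-8)
    stop("planted_covariance must be symmetric")
  ev <- eigen(planted_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("planted_covariance must be positive semidefinite")
  if (n_timepoints < 64) stop("n_timepoints must be >= 64")
  if (tr_seconds <= 0) stop("tr_seconds must be > 0")
  Sigma <- planted_covariance + diag(noise_sd^2, n_regions)
  with_seed(seed, {
    Y <- MASS::mvrnorm(n_timepoints, mu = rep(0, n_regions), Sigma = Sigma)
    structure(list(roi_ts = t(Y), tr_seconds = tr_seconds,
                   planted_covariance = planted_covariance,
                   noise_sd = noise_sd),
              class = "bold_series")
  })
}

#' @export
print.bold_series <- function(x, ...) {
  cat("bold_series:", nrow(x$roi_ts), "regions x", ncol(x$roi_ts),
      "timepoints, TR =", x$tr_seconds, "s\n")
  invisible(x)
}
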