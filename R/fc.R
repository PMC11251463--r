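#' Linear detrend and band-pass filter ROI time series
#'
#' Removes each ROI's linear trend (least-squares line, which also removes
#' the mean) and applies a zero-phase band-pass filter — a 2nd-order
#' Butterworth run forward and backward (`signal::filtfilt`) — with default
#' pass band 0.01-0.1 Hz. At TR = 3 s the Nyquist frequency is 1/6 Hz, so
#' the default band is admissible.
#'
#' @param ts a [generate_bold()] `bold_series`, or a region x timepoint
#'   matrix (then `tr_seconds` must be given).
#' @param low,high pass-band edges in Hz; require `0 < low < high <
#'   Nyquist`.
#' @param tr_seconds sampling interval when `ts` is a bare matrix.
#' @return A `bold_series` with filtered `roi_ts`.
#' @export
detrend_bandpass <- function(ts, low = 0.01, high = 0.1, tr_seconds = NULL) {
  if (inherits(ts, "bold_series")) {
    mat <- ts$roi_ts; tr <- ts$tr_seconds
  } else {
    mat <- as.matrix(ts)
    if (is.null(tr_seconds)) stop("tr_seconds required for a bare matrix")
    tr <- tr_seconds
  }
  T_len <- ncol(mat)
  if (T_len < 64) stop("series length must be >= 64")
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq))
    stop("need 0 < low < high < Nyquist (", format(nyq, digits = 4), " Hz)")
  tt <- seq_len(T_len)
  tt_c <- tt - mean(tt)
  # least-squares detrend: subtract intercept + slope * t per ROI
  slope <- (mat %*% tt_c) / sum(tt_c^2)
  detr <- mat - rowMeans(mat) - slope %*% t(tt_c)
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  filt <- t(apply(detr, 1L, function(x) signal::filtfilt(bf, x)))
  out <- if (inherits(ts, "bold_series")) ts else
    list(tr_seconds = tr, planted_covariance = NULL, noise_sd = NA_real_)
  out$roi_ts <- filt
  class(out) <- "bold_series"
  out
}

#' Pearson functional-connectivity matrix
#'
#' Pairwise Pearson correlations between ROI time courses. ROIs with zero
#' variance are flagged: their rows/columns are set to `NA` and listed in
#' the `excluded_rois` attribute so downstream degree aggregation can skip
#' them.
#'
#' @param ts `bold_series` or region x timepoint matrix.
#' @return N x N correlation matrix (symmetric, unit diagonal for retained
#'   ROIs) with attribute `excluded_rois`.
#' @export
fc_matrix <- function(ts) {
  mat <- if (inherits(ts, "bold_series")) ts$roi_ts else as.matrix(ts)
  v <- apply(mat, 1L, var)
  excluded <- which(v == 0 | !is.finite(v))
  r <- suppressWarnings(cor(t(mat)))
  if (length(excluded)) {
    r[excluded, ] <- NA_real_
    r[, excluded] <- NA_real_
  }
  diag(r)[setdiff(seq_len(nrow(mat)), excluded)] <- 1
  structure(r, excluded_rois = excluded)
}

#' Threshold a correlation matrix and compute weighted node degree
#'
#' Off-diagonal correlations below `tau` are set to 0; values at or above
#' `tau` are retained as edge weights. The degree of a node is the weighted
#' sum of its connections, excluding the self-correlation (the diagonal),
#' so with `tau = 0` degrees lie in [0, N-1]. Negative correlations are
#' zeroed at the default threshold.
#'
#' @param corr correlation matrix (e.g. from [fc_matrix()]).
#' @param tau correlation threshold (default 0).
#' @return List with `weights` (thresholded matrix, zero diagonal) and
#'   `degree` (per-node weighted sum; `NA` for excluded ROIs).
#' @export
#' @examples
#' r <- diag(3); r[1, 2] <- r[2, 1] <- 0.5
#' threshold_and_degree(r)$degree
threshold_and_degree <- function(corr, tau = 0) {
  corr <- as.matrix(corr)
  w <- corr
  w[w < tau] <- 0
  diag(w) <- 0
  degree <- rowSums(w, na.rm = FALSE)
  excl <- attr(corr, "excluded_rois")
  if (length(excl)) {
    w_na <- w
    w_na[is.na(w_na)] <- 0
    degree <- rowSums(w_na)
    degree[excl] <- NA_real_
  }
  list(weights = w, degree = degree)
}

#' Mean node degree within each cortical network
#'
#' Unweighted mean of node degrees over the nodes assigned to each of the
#' seven networks. Degrees are computed over the full connectivity matrix
#' (a node keeps its connections to all networks); aggregation averages
#' nodes, not edges. With `within_network_edges = TRUE` the degree of each
#' node is recomputed over within-network edges only before averaging.
#'
#' @param degree per-node degrees, or the list from
#'   [threshold_and_degree()] when `within_network_edges` is used.
#' @param network_labels character vector (or named vector), node ->
#'   network name; `NA` nodes are ignored.
#' @param within_network_edges restrict each node's degree to edges inside
#'   its own network (default `FALSE`).
#' @return Named numeric vector over [yeo7_networks()].
#' @export
network_degree <- function(degree, network_labels,
                           within_network_edges = FALSE) {
  nets <- yeo7_networks()
  if (within_network_edges) {
    if (!is.list(degree) || is.null(degree$weights))
      stop("within_network_edges needs the weights matrix from threshold_and_degree()")
    w <- degree$weights
    same <- outer(network_labels, network_labels, "==")
    same[is.na(same)] <- FALSE
    deg <- rowSums(w * same, na.rm = TRUE)
  } else {
    deg <- if (is.list(degree)) degree$degree else degree
  }
  if (length(deg) != length(network_labels))
    stop("degree and network_labels lengths differ")
  out <- setNames(numeric(length(nets)), nets)
  for (net in nets) {
    nodes <- which(!is.na(network_labels) & network_labels == net)
    out[net] <- if (length(nodes)) mean(deg[nodes], na.rm = TRUE) else NA_real_
  }
  out
}

#' Full functional-connectivity profile of one subject
#'
#' Convenience wrapper: detrend/band-pass, Pearson correlation, tau
#' thresholding, weighted degree, per-network mean degree.
#'
#' @param ts `bold_series`.
#' @param network_labels node -> network name.
#' @param tau correlation threshold (default 0).
#' @param low,high band edges in Hz.
#' @return Object of class `fc_profile`: `corr`, `weights`, `degree`,
#'   `network_degree`.
#' @export
fc_profile <- function(ts, network_labels, tau = 0, low = 0.01, high = 0.1) {
  filt <- detrend_bandpass(ts, low = low, high = high)
  r <- fc_matrix(filt)
  td <- threshold_and_degree(r, tau = tau)
  structure(list(corr = r, weights = td$weights, degree = td$degree,
                 network_degree = network_degree(td$degree, network_labels)),
            class = "fc_profile")
}

#' @export
print.fc_profile <- function(x, ...) {
  cat("fc_profile:", length(x$degree), "nodes; network degree:\n")
  print(round(x$network_degree, 3))
  invisible(x)
}
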