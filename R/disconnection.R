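#' Pairwise change-in-connectivity (disconnection) scores
#'
#' For every region pair (a, b), the score is the proportion of reference
#' streamlines connecting a and b that pass through lesioned tissue:
#' 0 = no disconnection, 1 = complete disconnection. A streamline is hit
#' when any of its voxels lies in the lesion mask (binary hit, no
#' partial-volume weighting). Pairs with no reference streamlines score 0
#' and are flagged in `no_streamline_pairs`.
#'
#' @param world a [generate_toy_world()] object (parcellation +
#'   streamlines).
#' @param lesion_mask integer vector of 1-based linear voxel indices; must
#'   lie within the grid.
#' @return Object of class `disconnection_matrix`: `scores` (N x N
#'   symmetric, zero diagonal, entries in [0, 1]), `streamline_counts`,
#'   `network_labels`, `no_streamline_pairs` (logical N x N).
#' @export
pairwise_disconnection <- function(world, lesion_mask) {
  stopifnot(inherits(world, "toy_world"))
  n_vox <- prod(world$grid_shape)
  lesion_mask <- as.integer(lesion_mask)
  if (length(lesion_mask) && (min(lesion_mask) < 1L || max(lesion_mask) > n_vox))
    stop("lesion voxel outside the grid")
  N <- max(world$parcellation)
  in_lesion <- logical(n_vox)
  in_lesion[lesion_mask] <- TRUE
  hits <- matrix(0, N, N)
  totals <- matrix(0, N, N)
  for (s in world$streamlines) {
    totals[s$a, s$b] <- totals[s$a, s$b] + 1
    if (any(in_lesion[s$voxels])) hits[s$a, s$b] <- hits[s$a, s$b] + 1
  }
  totals <- totals + t(totals)
  hits <- hits + t(hits)
  scores <- ifelse(totals > 0, hits / pmax(totals, 1), 0)
  diag(scores) <- 0
  no_sl <- totals == 0
  diag(no_sl) <- FALSE
  structure(list(scores = scores, streamline_counts = totals,
                 network_labels = world$network_labels,
                 no_streamline_pairs = no_sl),
            class = "disconnection_matrix")
}

#' @export
print.disconnection_matrix <- function(x, ...) {
  cat("disconnection_matrix:", nrow(x$scores), "regions, mean score",
      format(mean(x$scores[upper.tri(x$scores)]), digits = 4), "\n")
  invisible(x)
}

#' Average disconnection within each cortical network
#'
#' For each of the seven cortical networks, the unweighted mean of the
#' pairwise scores over all unordered pairs of distinct regions belonging
#' to that network. Pairs without reference streamlines contribute 0 by
#' default (keeps network means comparable across subjects sharing a
#' parcellation); set `drop_unconnected = TRUE` to average over connected
#' pairs only. Regions without a network label (subcortical/cerebellar
#' stand-ins) are ignored. Single-region networks have no within pairs and
#' return 0.
#'
#' @param dmat a [pairwise_disconnection()] result.
#' @param drop_unconnected drop zero-streamline pairs from the mean.
#' @return Named numeric vector over [yeo7_networks()], values in [0, 1].
#' @export
network_disconnection <- function(dmat, drop_unconnected = FALSE) {
  stopifnot(inherits(dmat, "disconnection_matrix"))
  labels <- dmat$network_labels
  nets <- yeo7_networks()
  out <- setNames(numeric(length(nets)), nets)
  for (net in nets) {
    regs <- as.integer(names(labels)[!is.na(labels) & labels == net])
    if (length(regs) < 2L) { out[net] <- 0; next }
    prs <- utils::combn(regs, 2L)
    vals <- dmat$scores[cbind(prs[1L, ], prs[2L, ])]
    if (drop_unconnected) {
      conn <- !dmat$no_streamline_pairs[cbind(prs[1L, ], prs[2L, ])]
      vals <- vals[conn]
      if (!length(vals)) { out[net] <- 0; next }
    }
    out[net] <- mean(vals)
  }
  out
}

#' Per-subject network disconnection table for a cohort
#'
#' Runs [pairwise_disconnection()] + [network_disconnection()] for each
#' subject's lesion mask against a shared toy world.
#'
#' @param lesion_masks named list, subject -> voxel-index vector.
#' @param world shared [generate_toy_world()] parcellation/streamlines.
#' @param drop_unconnected passed to [network_disconnection()].
#' @return `data.frame` with `subject_id` and one column per network; zero
#'   rows for an empty cohort.
#' @export
cohort_disconnection <- function(lesion_masks, world,
                                 drop_unconnected = FALSE) {
  nets <- yeo7_networks()
  if (length(lesion_masks) == 0L) {
    out <- as.data.frame(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(nets))),
      c("subject_id", nets)), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(lesion_masks, function(mask)
    network_disconnection(pairwise_disconnection(world, mask),
                          drop_unconnected = drop_unconnected))
  out <- as.data.frame(do.call(rbind, rows))
  ids <- names(lesion_masks)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(lesion_masks))
  out <- cbind(subject_id = ids, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
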