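#' Write / read a data frame as TSV
#'
#' Tab-separated values with a header row, no quoting, no row names — the
#' interchange format for every table the pipeline emits.
#'
#' @param df data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# matrices go out with row names in a leading column
write_matrix_tsv <- function(m, path, rowname_col = "row") {
  df <- data.frame(rn = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- rowname_col
  write_tsv(df, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export streamlines as JSON lines
#'
#' One JSON array per line: `[region_a, region_b, [[x, y, z], ...]]` with
#' 0-based integer voxel coordinates.
#'
#' @param world a [generate_toy_world()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_streamlines_jsonl <- function(world, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in world$streamlines) {
    xyz <- voxel_xyz(world, s$voxels)
    line <- jsonlite::toJSON(list(s$a, s$b, unname(split(
      as.integer(t(xyz)), rep(seq_len(nrow(xyz)), each = 3L)))),
      auto_unbox = TRUE)
    writeLines(line, con)
  }
  invisible(path)
}

#' Read streamlines from JSON lines
#'
#' Inverse of [write_streamlines_jsonl()]; voxel coordinates are converted
#' back to 1-based linear indices on the given grid.
#'
#' @param path JSON-lines file.
#' @param grid_shape 3-vector of grid dimensions.
#' @return List of `list(a, b, voxels)`.
#' @export
read_streamlines_jsonl <- function(path, grid_shape) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyMatrix = TRUE)
    xyz <- if (is.matrix(obj[[3L]])) obj[[3L]] else do.call(rbind, obj[[3L]])
    idx <- 1L + xyz[, 1L] + grid_shape[1L] * (xyz[, 2L] +
                                                grid_shape[2L] * xyz[, 3L])
    list(a = as.integer(obj[[1L]]), b = as.integer(obj[[2L]]),
         voxels = as.integer(idx))
  })
}

#' Write the toy parcellation or a lesion mask as NIfTI
#'
#' Optional NIfTI export (uint16 region labels / uint8 mask) via the RNifti
#' package; identity affine, 1 mm isotropic toy voxels.
#'
#' @param world a [generate_toy_world()] object.
#' @param path output `.nii`/`.nii.gz` path.
#' @param mask optional voxel-index vector; when given, a binary mask is
#'   written instead of the parcellation.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(world, path, mask = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package")
  if (is.null(mask)) {
    vol <- world$parcellation
    storage.mode(vol) <- "integer"
  } else {
    vol <- array(0L, dim = world$grid_shape)
    vol[mask] <- 1L
  }
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
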