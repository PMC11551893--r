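#' Construct a pattern dataset
#'
#' A pattern dataset couples a numeric observation-by-voxel matrix of
#' activation estimates (GLM beta weights or simulated equivalents) with a
#' label table describing each row. It is the unit every analysis in the
#' package consumes.
#'
#' @param patterns numeric matrix, one row per observation, one column per
#'   voxel.
#' @param labels data.frame aligned to rows of `patterns`; must contain
#'   columns `run`, `order`, `timing`, `phase`.
#' @param voxel_coordinates optional integer matrix (n_voxels x 3) mapping
#'   columns of `patterns` to positions on a 3D grid.
#' @return an object of class `pattern_dataset`.
#' @export
pattern_dataset <- function(patterns, labels, voxel_coordinates = NULL) {
  patterns <- as.matrix(patterns)
  if (!is.numeric(patterns)) stop("patterns must be numeric")
  if (ncol(patterns) < 2L) stop("a pattern dataset needs at least 2 voxels")
  if (nrow(patterns) != nrow(labels))
    stop("patterns and labels must have the same number of rows")
  need <- c("run", "order", "timing", "phase")
  if (!all(need %in% names(labels)))
    stop("labels must contain columns: ", paste(need, collapse = ", "))
  if (is.null(labels$sequence))
    labels$sequence <- sequence_id(labels$order, labels$timing)
  if (!is.null(voxel_coordinates)) {
    voxel_coordinates <- as.matrix(voxel_coordinates)
    if (nrow(voxel_coordinates) != ncol(patterns) ||
        ncol(voxel_coordinates) != 3L)
      stop("voxel_coordinates must be an n_voxels x 3 matrix")
  }
  structure(list(patterns = patterns, labels = labels,
                 voxel_coordinates = voxel_coordinates),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat("<pattern_dataset> ", nrow(x$patterns), " observations x ",
      ncol(x$patterns), " voxels\n", sep = "")
  cat("  runs: ", length(unique(x$labels$run)),
      "; phases: ", paste(unique(x$labels$phase), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$voxel_coordinates)) cat("  volumetric (grid coordinates attached)\n")
  invisible(x)
}

#' Number of voxels in a pattern dataset
#' @param ds a `pattern_dataset`.
#' @return integer voxel count.
#' @export
n_voxels <- function(ds) ncol(ds$patterns)

#' Restrict a pattern dataset to a subset of rows and/or voxels
#' @param ds a `pattern_dataset`.
#' @param rows,voxels index vectors (default: keep all).
#' @return a `pattern_dataset`.
#' @export
subset_dataset <- function(ds, rows = NULL, voxels = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(ds$patterns))
  if (is.null(voxels)) voxels <- seq_len(ncol(ds$patterns))
  pattern_dataset(ds$patterns[rows, voxels, drop = FALSE],
                  ds$labels[rows, , drop = FALSE],
                  if (!is.null(ds$voxel_coordinates))
                    ds$voxel_coordinates[voxels, , drop = FALSE])
}
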