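#' Write / read a pattern dataset as delimited text
#'
#' Patterns are stored as a tab-separated matrix and labels as a CSV with
#' columns `subject`, `run`, `order`, `timing`, `phase` (plus `sequence`).
#'
#' @param ds a `pattern_dataset`.
#' @param patterns_file,labels_file output paths.
#' @param subject subject identifier written into the labels table.
#' @return invisibly, the two paths.
#' @export
write_pattern_dataset <- function(ds, patterns_file, labels_file,
                                  subject = 1L) {
  utils::write.table(ds$patterns, patterns_file, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  lab <- cbind(subject = subject,
               ds$labels[, c("run", "order", "timing", "phase", "sequence")])
  utils::write.csv(lab, labels_file, row.names = FALSE)
  invisible(c(patterns_file, labels_file))
}

#' @rdname write_pattern_dataset
#' @return `read_pattern_dataset`: the reconstructed `pattern_dataset`.
#' @export
read_pattern_dataset <- function(patterns_file, labels_file) {
  X <- as.matrix(utils::read.table(patterns_file, sep = "\t"))
  dimnames(X) <- NULL
  lab <- utils::read.csv(labels_file, stringsAsFactors = FALSE)
  pattern_dataset(X, lab[, setdiff(names(lab), "subject"), drop = FALSE])
}

#' Write / read a volume mask as NIfTI
#'
#' The voxel size is carried in the NIfTI header (`pixdim`).
#'
#' @param mask a [volume_mask()].
#' @param file path to a `.nii` / `.nii.gz` file.
#' @return invisibly, the path.
#' @export
write_mask_nifti <- function(mask, file) {
  img <- RNifti::asNifti(array(as.numeric(mask$grid), dim(mask$grid)))
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_mask_nifti
#' @return `read_mask_nifti`: the reconstructed `volume_mask`.
#' @export
read_mask_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  volume_mask(array(as.vector(img) != 0, dim(img)),
              RNifti::pixdim(img)[1:3])
}

#' Write a statistical map as NIfTI on a mask's grid
#' @param map 3D numeric array (NA outside the mask becomes 0).
#' @param mask the `volume_mask` providing the grid and voxel size.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_map_nifti <- function(map, mask, file) {
  stopifnot(identical(dim(map), dim(mask$grid)))
  map[is.na(map)] <- 0
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write / read a simulation or pipeline configuration as YAML
#' @param cfg a `sim_config` or plain list.
#' @param file path to a `.yaml` file.
#' @return invisibly, the path.
#' @export
write_config_yaml <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname write_config_yaml
#' @return `read_sim_config_yaml`: a validated `sim_config`.
#' @export
read_sim_config_yaml <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(sim_config, raw[intersect(names(raw), names(formals(sim_config)))])
}

#' Write an RDM (or any labeled square matrix) as CSV
#' @param rdm an `rdm` object.
#' @param file output path.
#' @return invisibly, the path.
#' @export
write_rdm_csv <- function(rdm, file) {
  lab <- paste(rdm$conditions$sequence, rdm$conditions$phase, sep = ".")
  m <- rdm$distances
  dimnames(m) <- list(lab, lab)
  utils::write.csv(m, file)
  invisible(file)
}
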