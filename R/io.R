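# File I/O: NIfTI volumes, PNG photographs, CSV tables, YAML run configs.
# All formats are chosen lossless for the data they carry; volume
# round-trips preserve values and spacing exactly (float64 NIfTI).

#' Write a voxel volume to NIfTI
#'
#' @param vol a \code{\link{voxel_volume}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  hdr <- list(pixdim = c(-1, rep(vol$spacing_mm, 3), 0, 0, 0, 0))
  img <- RNifti::asNifti(vol$values, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a voxel volume from NIfTI
#'
#' Spacing is taken from the header; the volume must be 3-D and
#' isotropic.
#'
#' @param path a \code{.nii}/\code{.nii.gz} file.
#' @return a \code{\link{voxel_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot parse '%s' as NIfTI: %s",
                                 path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s': expected a 3-D volume, got %d dimensions",
                 path, length(d)))
  pd <- RNifti::pixdim(img)
  if (max(pd) - min(pd) > 1e-8 * max(pd))
    stop(sprintf("'%s': anisotropic spacing (%s) unsupported",
                 path, paste(signif(pd, 6), collapse = " x ")))
  voxel_volume(array(as.numeric(img), dim = d), spacing_mm = pd[1])
}

#' Write an RGB image to PNG
#'
#' @param image H x W x 3 array in [0, 1].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read an RGB image from PNG
#'
#' @param path input path.
#' @return H x W x 3 numeric array in [0, 1] (an alpha channel, if
#'   present, is dropped).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a data frame to CSV (header row, no row names)
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by \code{\link{write_table}}
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a run configuration as YAML
#'
#' @param config a \code{\link{run_config}} list.
#' @param path file path.
#' @return the config (read) or the path (write), invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
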