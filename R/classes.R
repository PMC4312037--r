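#' Voxel volume in Hounsfield units
#'
#' A 3-D scalar grid of CT numbers on the Hounsfield scale (water = 0,
#' air = -1000) with isotropic voxel spacing. This is the package's image
#' container; the scanner it emulates reconstructs at 77 um isotropic.
#'
#' @param values numeric 3-D array of HU values; all finite.
#' @param spacing_mm isotropic voxel edge length in mm (> 0).
#' @param origin_mm numeric length-3 vector, position of the first voxel
#'   center in mm.
#' @return an object of class \code{voxel_volume}: a list with elements
#'   \code{values}, \code{spacing_mm}, \code{origin_mm}.
#' @export
voxel_volume <- function(values, spacing_mm = 0.077, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (any(dim(values) < 1L)) stop("grid dimensions must all be >= 1")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("'spacing_mm' must be a single positive number")
  if (!all(is.finite(values))) stop("all HU values must be finite")
  if (length(origin_mm) != 3L) stop("'origin_mm' must have length 3")
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %.4g mm isotropic\n",
              d[1], d[2], d[3], x$spacing_mm))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Tissue label mask
#'
#' Integer companion grid to a \code{\link{voxel_volume}} with codes
#' 0 = background, 1 = myocardium, 2 = LV blood pool, 3 = infarct.
#' Infarct voxels are anatomically part of the myocardial wall; the code
#' distinguishes them so segmentations can be scored against ground truth.
#'
#' @param labels integer 3-D array drawn from \{0, 1, 2, 3\}.
#' @param spacing_mm isotropic voxel edge length in mm.
#' @return an object of class \code{label_mask}.
#' @export
label_mask <- function(labels, spacing_mm = 0.077) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array")
  if (!all(labels %in% 0:3))
    stop("labels must be drawn from {0, 1, 2, 3}")
  structure(
    list(labels = labels, spacing_mm = spacing_mm),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cnt <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf("<label_mask> %d x %d x %d voxels @ %.4g mm\n",
              d[1], d[2], d[3], x$spacing_mm))
  cat(sprintf("  background %d | myocardium %d | blood %d | infarct %d\n",
              cnt[1], cnt[2], cnt[3], cnt[4]))
  invisible(x)
}

# label codes used throughout
LBL_BACKGROUND <- 0L
LBL_MYOCARDIUM <- 1L
LBL_BLOOD      <- 2L
LBL_INFARCT    <- 3L
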