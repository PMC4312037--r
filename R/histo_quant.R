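# Quantification of infarct fraction from TTC-stained slice photographs.
#
# Viable myocardium stains brick red (strongly saturated, dark); infarct
# stays pale pink (weakly saturated, light); the photographic background
# is near-white. Classification therefore works in a saturation/lightness
# space rather than on raw RGB.

# per-pixel HSV saturation and HSL lightness of an H x W x 3 array in [0,1]
.sat_lum <- function(image) {
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  list(sat = sat, lum = (mx + mn) / 2)
}

#' Viability classification thresholds
#'
#' @param infarct_sat_max HSV saturation below which tissue is pale
#'   (default 0.35).
#' @param infarct_lum_min HSL lightness above which tissue is pale
#'   (default 0.55).
#' @param bg_lum_min,bg_sat_max lightness/saturation bounds defining the
#'   near-white photographic background (defaults 0.88 and 0.12).
#' @return a plain list of thresholds.
#' @export
histology_thresholds <- function(infarct_sat_max = 0.35,
                                 infarct_lum_min = 0.55,
                                 bg_lum_min = 0.88, bg_sat_max = 0.12) {
  list(infarct_sat_max = infarct_sat_max, infarct_lum_min = infarct_lum_min,
       bg_lum_min = bg_lum_min, bg_sat_max = bg_sat_max)
}

#' Segment tissue from the photographic background
#'
#' Pixels that are not near-white (by lightness and saturation) form the
#' tissue candidate set; only the largest connected component is kept,
#' discarding stray jitter pixels.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param pixel_size_mm physical pixel size (unused by the masking itself;
#'   kept so callers carry the scale with the mask).
#' @param thresholds a \code{\link{histology_thresholds}} list.
#' @return logical H x W tissue mask.
#' @export
segment_tissue <- function(image, pixel_size_mm = NULL,
                           thresholds = histology_thresholds()) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("'image' must be an H x W x 3 RGB array")
  sl <- .sat_lum(image)
  tissue <- !(sl$lum > thresholds$bg_lum_min &
                sl$sat < thresholds$bg_sat_max)
  if (!any(tissue)) stop("blank image: no tissue found")
  d <- dim(tissue)
  m3 <- array(tissue, dim = c(d, 1L))
  keep <- .largest_component(m3, 6L)
  matrix(keep[, , 1], nrow = d[1])
}

#' Area of a 2-D mask
#'
#' @param mask logical matrix.
#' @param pixel_size_mm pixel edge length in mm.
#' @return area in mm^2.
#' @export
mask_area_mm2 <- function(mask, pixel_size_mm) {
  if (pixel_size_mm <= 0) stop("'pixel_size_mm' must be > 0")
  sum(mask) * pixel_size_mm^2
}

#' Classify tissue pixels as viable or infarcted
#'
#' Within the tissue mask, pale pixels (saturation below
#' \code{infarct_sat_max} and lightness above \code{infarct_lum_min}) are
#' infarct; the rest are viable. The two masks partition the tissue mask.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param tissue_mask logical matrix from \code{\link{segment_tissue}}.
#' @param thresholds a \code{\link{histology_thresholds}} list.
#' @return list \code{(viable, infarct)} of logical matrices.
#' @export
classify_viability <- function(image, tissue_mask,
                               thresholds = histology_thresholds()) {
  if (!any(tissue_mask)) stop("empty tissue mask")
  sl <- .sat_lum(image)
  infarct <- tissue_mask & sl$sat < thresholds$infarct_sat_max &
    sl$lum > thresholds$infarct_lum_min
  list(viable = tissue_mask & !infarct, infarct = infarct)
}

#' Measure one histology slice
#'
#' Runs tissue segmentation and viability classification on the front and
#' back face photographs of a slab.
#'
#' @param slice a \code{histology_slice} (see
#'   \code{\link{render_ttc_slices}}) or any list with
#'   \code{front_image}, \code{back_image}, \code{pixel_size_mm},
#'   \code{thickness_mm}.
#' @param thresholds a \code{\link{histology_thresholds}} list.
#' @return list of class \code{slice_measurement}:
#'   \code{tissue_area_front_mm2}, \code{tissue_area_back_mm2},
#'   \code{infarct_area_front_mm2}, \code{infarct_area_back_mm2},
#'   \code{thickness_mm}.
#' @export
measure_slice <- function(slice, thresholds = histology_thresholds()) {
  px <- slice$pixel_size_mm
  one_face <- function(img) {
    tis <- segment_tissue(img, px, thresholds)
    cls <- classify_viability(img, tis, thresholds)
    c(tissue = mask_area_mm2(tis, px),
      infarct = mask_area_mm2(cls$infarct, px))
  }
  f <- one_face(slice$front_image)
  b <- one_face(slice$back_image)
  structure(
    list(tissue_area_front_mm2 = f[["tissue"]],
         tissue_area_back_mm2 = b[["tissue"]],
         infarct_area_front_mm2 = f[["infarct"]],
         infarct_area_back_mm2 = b[["infarct"]],
         thickness_mm = slice$thickness_mm),
    class = "slice_measurement"
  )
}

#' Infarct percent of the myocardium from slice measurements
#'
#' Each slab contributes the mean of its front and back face areas times
#' its thickness (photographing both faces of a 1 mm slab gives an
#' effective 0.5 mm out-of-plane resolution). Reporting infarct volume as
#' a percentage of total myocardium volume cancels uniform tissue
#' shrinkage.
#'
#' @param slices list of \code{slice_measurement} objects (at least one),
#'   or of \code{histology_slice} objects, which are measured first with
#'   default thresholds.
#' @param thickness_mm slab thickness; defaults to the thickness recorded
#'   in the measurements.
#' @return percent infarct in [0, 100].
#' @export
percent_infarct_histology <- function(slices, thickness_mm = NULL) {
  if (length(slices) < 1L) stop("need at least one slice")
  slices <- lapply(slices, function(s) {
    if (inherits(s, "slice_measurement")) s else measure_slice(s)
  })
  th <- function(s) if (is.null(thickness_mm)) s$thickness_mm else thickness_mm
  inf_vol <- sum(vapply(slices, function(s)
    (s$infarct_area_front_mm2 + s$infarct_area_back_mm2) / 2 * th(s), 0))
  tis_vol <- sum(vapply(slices, function(s)
    (s$tissue_area_front_mm2 + s$tissue_area_back_mm2) / 2 * th(s), 0))
  if (tis_vol <= 0) stop("zero total tissue volume")
  100 * inf_vol / tis_vol
}
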