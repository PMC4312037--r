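# Rendering of TTC-stained slice photographs from the phantom label field.
#
# TTC turns viable myocardium brick red; necrotic (infarcted) tissue stays
# pale pink. The renderer slices the anatomical label field along the long
# axis, photographs both faces of each slab, and records the true areas so
# the color-segmentation pipeline can be scored against them.

.TTC_VIABLE  <- c(180, 40, 50) / 255
.TTC_INFARCT <- c(235, 190, 190) / 255
.TTC_JITTER_SD <- 10 / 255

# Anatomical labels of one cut plane, evaluated from the continuous
# phantom geometry at the exact cut height (a knife cut is not quantized
# to the imaging grid).
.face_labels <- function(spec, xs, ys, z) {
  cav <- spec$lv_cavity_semiaxes_dia_mm
  outer_ax <- cav + spec$wall_thickness_mm
  qin <- outer((xs / cav[1])^2, (ys / cav[2])^2, "+") + (z / cav[3])^2
  qout <- outer((xs / outer_ax[1])^2, (ys / outer_ax[2])^2, "+") +
    (z / outer_ax[3])^2
  lab <- matrix(LBL_BACKGROUND, length(xs), length(ys))
  lab[qout <= 1] <- LBL_MYOCARDIUM
  lab[qin <= 1] <- LBL_BLOOD
  w <- spec$infarct_wedge
  width <- w$azimuth_end_deg - w$azimuth_start_deg
  if (width > 0 && w$apical_extent_fraction > 0) {
    zcut <- -outer_ax[3] + w$apical_extent_fraction * 2 * outer_ax[3]
    if (z <= zcut) {
      az <- outer(xs, ys, function(x, y) atan2(y, x) * 180 / pi)
      in_az <- az >= w$azimuth_start_deg & az <= w$azimuth_end_deg
      if (width >= 360) in_az[] <- TRUE
      lab[in_az & lab == LBL_MYOCARDIUM] <- LBL_INFARCT
    }
  }
  lab
}

# render one cut plane as an RGB image at pixel_size_mm
.render_face <- function(spec, z, pixel_size_mm) {
  outer_ax <- spec$lv_cavity_semiaxes_dia_mm + spec$wall_thickness_mm
  half_n <- ceiling((outer_ax[1:2] + 0.3) / pixel_size_mm)
  xs <- (-half_n[1]:half_n[1]) * pixel_size_mm
  ys <- (-half_n[2]:half_n[2]) * pixel_size_mm
  plane <- .face_labels(spec, xs, ys, z)
  img <- array(1, dim = c(dim(plane), 3))   # white background (and cavity)
  for (ch in 1:3) {
    chan <- img[, , ch]
    chan[plane == LBL_MYOCARDIUM] <- .TTC_VIABLE[ch]
    chan[plane == LBL_INFARCT] <- .TTC_INFARCT[ch]
    img[, , ch] <- chan
  }
  list(image = img,
       infarct_area_mm2 = sum(plane == LBL_INFARCT) * pixel_size_mm^2,
       tissue_area_mm2 = sum(plane == LBL_INFARCT | plane == LBL_MYOCARDIUM) *
         pixel_size_mm^2)
}

.jitter_image <- function(img, sd) {
  if (sd <= 0) return(img)
  out <- img + array(stats::rnorm(length(img), 0, sd), dim = dim(img))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Render TTC-stained histology slices of a phantom heart
#'
#' Cuts the phantom's diastolic anatomy into short-axis slabs of the given
#' thickness and renders an RGB photograph of the front (lower, apical-side)
#' and back face of each slab, evaluating the anatomy continuously at the
#' exact cut heights (a knife cut is not quantized to the imaging grid):
#' viable myocardium brick red
#' (RGB ~ 180, 40, 50), infarct pale pink (~ 235, 190, 190), background
#' and cavity white, with per-pixel Gaussian color jitter. The true
#' infarct and tissue areas of each face are recorded from the label field
#' before jitter.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param thickness_mm slab thickness (default 1.0 mm, the knife setting
#'   used in the bench protocol); must be >= the voxel spacing.
#' @param pixel_size_mm photograph pixel size in mm.
#' @param seed integer seed for the color jitter.
#' @param jitter_sd per-channel jitter SD on the [0, 1] color scale
#'   (default 10/255).
#' @return list of \code{histology_slice} objects with fields
#'   \code{front_image}, \code{back_image} (H x W x 3 arrays in [0, 1]),
#'   \code{pixel_size_mm}, \code{thickness_mm},
#'   \code{true_infarct_area_front_mm2}, \code{true_infarct_area_back_mm2},
#'   \code{true_tissue_area_front_mm2}, \code{true_tissue_area_back_mm2}.
#' @export
render_ttc_slices <- function(spec, thickness_mm = 1.0,
                              pixel_size_mm = 0.05, seed = spec$seed,
                              jitter_sd = .TTC_JITTER_SD) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (thickness_mm <= 0 || pixel_size_mm <= 0)
    stop("'thickness_mm' and 'pixel_size_mm' must be > 0")
  if (thickness_mm < spec$spacing_mm)
    stop("'thickness_mm' must be at least the voxel spacing")
  co <- spec$lv_cavity_semiaxes_dia_mm[3] + spec$wall_thickness_mm
  n_slices <- ceiling(2 * co / thickness_mm)
  set.seed(seed)
  out <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    z_lo <- -co + (s - 1) * thickness_mm
    z_hi <- min(co, z_lo + thickness_mm)
    front <- .render_face(spec, z_lo, pixel_size_mm)
    back <- .render_face(spec, z_hi, pixel_size_mm)
    out[[s]] <- structure(
      list(front_image = .jitter_image(front$image, jitter_sd),
           back_image = .jitter_image(back$image, jitter_sd),
           pixel_size_mm = pixel_size_mm,
           thickness_mm = thickness_mm,
           true_infarct_area_front_mm2 = front$infarct_area_mm2,
           true_infarct_area_back_mm2 = back$infarct_area_mm2,
           true_tissue_area_front_mm2 = front$tissue_area_mm2,
           true_tissue_area_back_mm2 = back$tissue_area_mm2),
      class = "histology_slice"
    )
  }
  out
}

#' @export
print.histology_slice <- function(x, ...) {
  d <- dim(x$front_image)
  cat(sprintf("<histology_slice> %d x %d px @ %.3g mm | %.2g mm thick | true infarct %.2f / %.2f mm^2 (front/back)\n",
              d[1], d[2], x$pixel_size_mm, x$thickness_mm,
              x$true_infarct_area_front_mm2, x$true_infarct_area_back_mm2))
  invisible(x)
}
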