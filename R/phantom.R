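#' Calibrate a mono-exponential contrast washout curve
#'
#' Fits HU(t) = A0 * exp(-lambda * t) exactly through two measured
#' (time, HU) pairs, the standard tracer-kinetic description of iodinated
#' contrast clearing from a tissue compartment. Two time points determine
#' the curve uniquely.
#'
#' @param hu_early,hu_late mean HU of the tissue at the two acquisitions
#'   (both > 0).
#' @param t_early_min,t_late_min acquisition times in minutes after
#'   contrast administration (\code{t_late_min > t_early_min}).
#' @return named numeric vector \code{c(A0, lambda)} with \code{A0} in HU
#'   and \code{lambda} in 1/min (>= 0).
#' @examples
#' calibrate_washout(411, 245, 13, 30)   # blood-pool clearance
#' @export
calibrate_washout <- function(hu_early, hu_late, t_early_min, t_late_min) {
  if (!is.finite(hu_early) || !is.finite(hu_late) ||
      hu_early <= 0 || hu_late <= 0)
    stop("HU values must be positive and finite")
  if (!(t_late_min > t_early_min))
    stop("'t_late_min' must exceed 't_early_min'")
  if (hu_late > hu_early)
    stop("hu_late > hu_early: washout cannot have negative decay rate")
  lambda <- log(hu_early / hu_late) / (t_late_min - t_early_min)
  A0 <- hu_early * exp(lambda * t_early_min)
  c(A0 = A0, lambda = lambda)
}

#' Per-tissue washout model
#'
#' Bundles mono-exponential washout parameters for the three enhancing
#' tissues seen after a bolus of a small-molecule iodinated agent: LV blood,
#' infarcted myocardium (delayed enhancement: the agent is retained in
#' necrotic tissue), and viable myocardium.
#'
#' @param blood,infarct,myocardium numeric \code{c(A0, lambda)} pairs as
#'   returned by \code{\link{calibrate_washout}}.
#' @return object of class \code{washout_model}.
#' @export
washout_model <- function(blood, infarct, myocardium) {
  chk <- function(p, nm) {
    if (length(p) != 2L || p[1] <= 0 || p[2] < 0)
      stop(sprintf("'%s' must be c(A0 > 0, lambda >= 0)", nm))
    c(A0 = unname(p[1]), lambda = unname(p[2]))
  }
  structure(
    list(blood = chk(blood, "blood"), infarct = chk(infarct, "infarct"),
         myocardium = chk(myocardium, "myocardium")),
    class = "washout_model"
  )
}

#' Default washout model calibrated to the measured two-point HU data
#'
#' Blood 411 -> 245 HU, infarct 431 -> 281 HU, viable myocardium
#' 182 -> 139 HU between the first (13 min) and second (30 min)
#' post-injection acquisitions.
#'
#' @return a \code{\link{washout_model}}.
#' @export
default_washout <- function() {
  washout_model(
    blood      = calibrate_washout(411, 245, 13, 30),
    infarct    = calibrate_washout(431, 281, 13, 30),
    myocardium = calibrate_washout(182, 139, 13, 30)
  )
}

#' Evaluate a washout curve
#'
#' @param params \code{c(A0, lambda)} for one tissue, or a
#'   \code{\link{washout_model}} together with \code{tissue}.
#' @param t_min time in minutes after administration (>= 0).
#' @param tissue when \code{params} is a \code{washout_model}: one of
#'   \code{"blood"}, \code{"infarct"}, \code{"myocardium"}.
#' @return HU at \code{t_min}.
#' @export
washout_hu <- function(params, t_min, tissue = NULL) {
  if (any(t_min < 0)) stop("'t_min' must be non-negative")
  if (inherits(params, "washout_model")) {
    if (is.null(tissue)) stop("'tissue' required with a washout_model")
    params <- params[[match.arg(tissue, c("blood", "infarct", "myocardium"))]]
  }
  unname(params[1]) * exp(-unname(params[2]) * t_min)
}

# analytic volume of an axis-aligned ellipsoid below the plane z = Z
.ellipsoid_vol_below <- function(Z, a, b, c) {
  Z <- pmin(pmax(Z, -c), c)
  pi * a * b * (Z - Z^3 / (3 * c^2) + 2 * c / 3)
}

#' Infarct wedge sized to a target fraction of the myocardium
#'
#' LAD-territory infarcts are modeled as an anterior azimuthal wedge of the
#' wall extending from the apex. Given a target infarct fraction of the
#' myocardial shell, this fixes the apical extent and solves for the
#' azimuthal width from the analytic shell-cap volumes.
#'
#' @param dia_semiaxes_mm diastolic cavity semiaxes (mm).
#' @param wall_thickness_mm wall thickness (mm).
#' @param fraction target infarct fraction of the shell, in [0, ~0.6].
#' @param apical_extent_fraction fraction of the long axis, measured from
#'   the apex, that the wedge spans (default 0.65).
#' @return list(azimuth_start_deg, azimuth_end_deg, apical_extent_fraction).
#' @export
infarct_wedge_for_fraction <- function(dia_semiaxes_mm, wall_thickness_mm,
                                       fraction,
                                       apical_extent_fraction = 0.65) {
  if (fraction < 0) stop("'fraction' must be >= 0")
  if (fraction == 0)
    return(list(azimuth_start_deg = 0, azimuth_end_deg = 0,
                apical_extent_fraction = 0))
  a <- dia_semiaxes_mm[1]; b <- dia_semiaxes_mm[2]; c <- dia_semiaxes_mm[3]
  ao <- a + wall_thickness_mm; bo <- b + wall_thickness_mm
  co <- c + wall_thickness_mm
  shell_total <- 4 / 3 * pi * (ao * bo * co - a * b * c)
  Z <- -co + apical_extent_fraction * 2 * co
  shell_below <- .ellipsoid_vol_below(Z, ao, bo, co) -
    .ellipsoid_vol_below(Z, a, b, c)
  width_deg <- 360 * fraction * shell_total / shell_below
  if (width_deg > 360)
    stop("target infarct fraction not reachable with this apical extent")
  list(azimuth_start_deg = -width_deg / 2, azimuth_end_deg = width_deg / 2,
       apical_extent_fraction = apical_extent_fraction)
}

#' Specification of a synthetic heart
#'
#' The left ventricle is modeled as a pair of confocal ellipsoids: the
#' cavity (blood pool) and an epicardial surface offset by the wall
#' thickness. Systole shrinks the cavity isotropically so that
#' 1 - V_sys/V_dia equals the requested ejection fraction; the epicardial
#' surface is held fixed, so the wall thickens in systole as real
#' myocardium does. The infarct is an anterior azimuthal wedge of the wall
#' extending from the apex.
#'
#' @param lv_cavity_semiaxes_dia_mm diastolic cavity semiaxes (mm), all > 0.
#' @param true_ef ground-truth ejection fraction in [0, 1).
#' @param lv_cavity_semiaxes_sys_mm systolic semiaxes; defaults to the
#'   diastolic semiaxes scaled by (1 - true_ef)^(1/3). If supplied, must be
#'   volumetrically consistent with \code{true_ef} to within 0.02.
#' @param wall_thickness_mm myocardial wall thickness at diastole (mm).
#' @param infarct_wedge list(azimuth_start_deg, azimuth_end_deg,
#'   apical_extent_fraction); a zero-width wedge means no infarct.
#' @param washout a \code{\link{washout_model}}.
#' @param noise_sd_hu per-voxel additive Gaussian noise SD in HU.
#' @param background_hu HU of surrounding soft tissue (default 50).
#' @param spacing_mm isotropic voxel spacing (default 0.077, the scanner's
#'   reconstructed resolution).
#' @param seed integer seed controlling the phantom's noise realization.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(lv_cavity_semiaxes_dia_mm = c(1.7, 1.7, 3.0),
                         true_ef = 0.36,
                         lv_cavity_semiaxes_sys_mm = NULL,
                         wall_thickness_mm = 1.0,
                         infarct_wedge = list(azimuth_start_deg = -60,
                                              azimuth_end_deg = 60,
                                              apical_extent_fraction = 0.65),
                         washout = default_washout(),
                         noise_sd_hu = 30,
                         background_hu = 50,
                         spacing_mm = 0.077,
                         seed = 1L) {
  dia <- as.numeric(lv_cavity_semiaxes_dia_mm)
  if (length(dia) != 3L || any(dia <= 0)) stop("diastolic semiaxes must be 3 positive numbers")
  if (true_ef < 0 || true_ef >= 1) stop("'true_ef' must lie in [0, 1)")
  if (is.null(lv_cavity_semiaxes_sys_mm)) {
    sys <- dia * (1 - true_ef)^(1 / 3)
  } else {
    sys <- as.numeric(lv_cavity_semiaxes_sys_mm)
    if (length(sys) != 3L || any(sys <= 0)) stop("systolic semiaxes must be 3 positive numbers")
    ef_geo <- 1 - prod(sys) / prod(dia)
    if (abs(ef_geo - true_ef) > 0.02)
      stop("systolic semiaxes inconsistent with 'true_ef'")
  }
  if (prod(sys) >= prod(dia) && true_ef > 0)
    stop("systolic cavity volume must be smaller than diastolic")
  if (wall_thickness_mm <= 0) stop("'wall_thickness_mm' must be > 0")
  if (noise_sd_hu < 0) stop("'noise_sd_hu' must be >= 0")
  if (spacing_mm <= 0) stop("'spacing_mm' must be > 0")
  stopifnot(inherits(washout, "washout_model"))
  structure(
    list(lv_cavity_semiaxes_dia_mm = dia,
         lv_cavity_semiaxes_sys_mm = sys,
         true_ef = true_ef,
         wall_thickness_mm = wall_thickness_mm,
         infarct_wedge = infarct_wedge,
         washout = washout,
         noise_sd_hu = noise_sd_hu,
         background_hu = background_hu,
         spacing_mm = spacing_mm,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> EF %.2f | cavity dia (%.2f, %.2f, %.2f) mm | wall %.2f mm\n",
              x$true_ef, x$lv_cavity_semiaxes_dia_mm[1],
              x$lv_cavity_semiaxes_dia_mm[2], x$lv_cavity_semiaxes_dia_mm[3],
              x$wall_thickness_mm))
  w <- x$infarct_wedge
  cat(sprintf("  infarct wedge %.1f..%.1f deg, apical extent %.2f | noise %.0f HU | %.3f mm voxels\n",
              w$azimuth_start_deg, w$azimuth_end_deg,
              w$apical_extent_fraction, x$noise_sd_hu, x$spacing_mm))
  invisible(x)
}

# anatomical label field for one cardiac phase; voxel centers decide labels
.phantom_labels <- function(spec, phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  cav <- if (phase == "diastole") spec$lv_cavity_semiaxes_dia_mm
         else spec$lv_cavity_semiaxes_sys_mm
  dia <- spec$lv_cavity_semiaxes_dia_mm
  wall <- spec$wall_thickness_mm
  sp <- spec$spacing_mm
  if (wall < 2 * sp)
    stop("voxel spacing too coarse to resolve the wall (need wall >= 2 * spacing)")
  outer_ax <- dia + wall
  pad <- 3 * sp
  half_n <- ceiling((outer_ax + pad) / sp)
  xs <- (-half_n[1]:half_n[1]) * sp
  ys <- (-half_n[2]:half_n[2]) * sp
  zs <- (-half_n[3]:half_n[3]) * sp
  qx_in <- (xs / cav[1])^2; qy_in <- (ys / cav[2])^2; qz_in <- (zs / cav[3])^2
  qx_out <- (xs / outer_ax[1])^2; qy_out <- (ys / outer_ax[2])^2
  qz_out <- (zs / outer_ax[3])^2
  Qin <- outer(outer(qx_in, qy_in, "+"), qz_in, "+")
  Qout <- outer(outer(qx_out, qy_out, "+"), qz_out, "+")
  lab <- array(LBL_BACKGROUND, dim = dim(Qin))
  lab[Qout <= 1] <- LBL_MYOCARDIUM
  lab[Qin <= 1] <- LBL_BLOOD
  w <- spec$infarct_wedge
  width <- w$azimuth_end_deg - w$azimuth_start_deg
  if (width > 0 && w$apical_extent_fraction > 0) {
    az2d <- outer(xs, ys, function(x, y) atan2(y, x) * 180 / pi)
    in_az2d <- az2d >= w$azimuth_start_deg & az2d <= w$azimuth_end_deg
    # wedges wider than 180 deg wrap across the +/-180 boundary
    if (width >= 360) in_az2d[] <- TRUE
    zcut <- -outer_ax[3] + w$apical_extent_fraction * 2 * outer_ax[3]
    in_z <- zs <= zcut
    wedge <- array(FALSE, dim = dim(lab))
    wedge[, , in_z] <- in_az2d
    lab[wedge & lab == LBL_MYOCARDIUM] <- LBL_INFARCT
  }
  list(labels = lab, spacing_mm = sp,
       origin_mm = c(xs[1], ys[1], zs[1]))
}

#' Build a synthetic gated cardiac CT volume with ground-truth labels
#'
#' Renders the phantom's anatomy at one cardiac phase and one
#' post-injection time point. Each voxel receives the washout-model HU of
#' its tissue plus optional Gaussian noise; background soft tissue sits at
#' a fixed HU.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param phase \code{"diastole"} or \code{"systole"}.
#' @param t_min minutes after contrast administration (>= 0).
#' @param seed noise seed; defaults to \code{spec$seed}.
#' @param agent \code{"iohexol"} (small-molecule agent: the infarct shows
#'   delayed enhancement at its own washout level) or \code{"blood_pool"}
#'   (intravascular lipid agent: necrotic wall does not enhance, so the
#'   infarct renders at viable-myocardium HU). Ejection-fraction imaging
#'   uses the blood-pool agent.
#' @return list with components \code{volume} (\code{\link{voxel_volume}}),
#'   \code{mask} (\code{\link{label_mask}}), and \code{truth}: per-label
#'   voxel counts and volumes (mm^3), plus the infarct percent of the wall.
#' @export
build_heart_phantom <- function(spec, phase = c("diastole", "systole"),
                                t_min = 13, seed = spec$seed,
                                agent = c("iohexol", "blood_pool")) {
  phase <- match.arg(phase)
  agent <- match.arg(agent)
  if (t_min < 0) stop("'t_min' must be >= 0")
  geo <- .phantom_labels(spec, phase)
  lab <- geo$labels
  hu_blood <- washout_hu(spec$washout, t_min, "blood")
  hu_myo <- washout_hu(spec$washout, t_min, "myocardium")
  hu_inf <- if (agent == "iohexol") washout_hu(spec$washout, t_min, "infarct")
            else hu_myo
  vals <- array(spec$background_hu, dim = dim(lab))
  vals[lab == LBL_MYOCARDIUM] <- hu_myo
  vals[lab == LBL_BLOOD] <- hu_blood
  vals[lab == LBL_INFARCT] <- hu_inf
  if (spec$noise_sd_hu > 0) {
    set.seed(seed)
    vals <- vals + array(stats::rnorm(length(vals), 0, spec$noise_sd_hu),
                         dim = dim(vals))
  }
  cnt <- tabulate(lab + 1L, nbins = 4L)
  vox <- spec$spacing_mm^3
  wall_vox <- cnt[2] + cnt[4]
  truth <- list(
    n_voxels = c(background = cnt[1], myocardium = cnt[2],
                 blood = cnt[3], infarct = cnt[4]),
    volume_mm3 = c(background = cnt[1], myocardium = cnt[2],
                   blood = cnt[3], infarct = cnt[4]) * vox,
    percent_infarct = if (wall_vox > 0) 100 * cnt[4] / wall_vox else NA_real_
  )
  list(volume = voxel_volume(vals, geo$spacing_mm, geo$origin_mm),
       mask = label_mask(lab, geo$spacing_mm),
       truth = truth)
}

#' Corrupt a volume with bright motion streaks
#'
#' Emulates the linear hyper-intense artifacts produced by residual
#' cardiorespiratory motion under suboptimal gating, which a
#' threshold-based infarct segmentation misreads as enhancement. Streaks
#' are oriented in-plane lines of elevated HU spanning a band of slices.
#'
#' @param vol a \code{\link{voxel_volume}}.
#' @param severity >= 0; streak amplitude is proportional to it
#'   (300 HU at severity 1). Zero returns the input unchanged.
#' @param seed integer seed for streak placement.
#' @param n_streaks number of streak lines (default 12).
#' @return a \code{\link{voxel_volume}}.
#' @export
add_motion_streaks <- function(vol, severity, seed = 1L, n_streaks = 12L) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (severity < 0) stop("'severity' must be >= 0")
  if (severity == 0) return(vol)
  d <- dim(vol$values)
  sp <- vol$spacing_mm
  set.seed(seed)
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp
  ys <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp
  amp <- 300 * severity
  vals <- vol$values
  R <- 0.6 * min(max(abs(xs)), max(abs(ys)))
  for (s in seq_len(n_streaks)) {
    phi <- stats::runif(1, 0, pi)
    off <- stats::runif(1, -R, R)
    Dist <- abs(outer(xs * cos(phi), ys * sin(phi), "+") - off)
    prof <- pmax(0, 1 - Dist / sp)       # ~2-voxel-wide triangular profile
    zc <- sample.int(d[3], 1)
    zh <- max(1L, round(0.2 * d[3]))
    zidx <- max(1L, zc - zh):min(d[3], zc + zh)
    vals[, , zidx] <- vals[, , zidx] +
      array(amp * prof, dim = c(d[1], d[2], length(zidx)))
  }
  voxel_volume(vals, vol$spacing_mm, vol$origin_mm)
}

# truncated-normal draw by rejection
.rtruncnorm1 <- function(mean, sd, lower, upper) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower && x < upper) return(x)
  }
}

#' Simulate a study cohort of phantom specifications
#'
#' Ischemia-reperfusion (IR) subjects draw their true ejection fraction
#' from Normal(0.36, 0.11) truncated to (0.05, 0.95) and their infarct
#' fraction of the wall from Normal(0.32, 0.08) truncated to (0, 0.6);
#' controls draw EF from Normal(0.59, 0.07) and carry no infarct. These are
#' the group means and SDs measured in the animal study the pipeline
#' emulates.
#'
#' @param n_ir,n_control subject counts (>= 0).
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{phantom_spec}}
#'   (e.g. \code{spacing_mm}, \code{noise_sd_hu}).
#' @return list of \code{\link{phantom_spec}} objects, each carrying
#'   \code{$subject_id}, \code{$group} ("IR" or "control") and
#'   \code{$target_infarct_fraction}.
#' @export
simulate_cohort <- function(n_ir = 8L, n_control = 7L, seed = 1L, ...) {
  if (n_ir < 0 || n_control < 0) stop("cohort counts must be >= 0")
  set.seed(seed)
  extra <- list(...)
  specs <- vector("list", n_ir + n_control)
  for (i in seq_len(n_ir + n_control)) {
    ir <- i <= n_ir
    ef <- if (ir) .rtruncnorm1(0.36, 0.11, 0.05, 0.95)
          else .rtruncnorm1(0.59, 0.07, 0.05, 0.95)
    inf_frac <- if (ir) .rtruncnorm1(0.32, 0.08, 0, 0.6) else 0
    sub_seed <- sample.int(2147483000L, 1)   # headroom for derived seeds
    args <- c(list(true_ef = ef, seed = sub_seed), extra)
    sp <- do.call(phantom_spec, args)
    sp$infarct_wedge <- infarct_wedge_for_fraction(
      sp$lv_cavity_semiaxes_dia_mm, sp$wall_thickness_mm, inf_frac)
    sp$subject_id <- i
    sp$group <- if (ir) "IR" else "control"
    sp$target_infarct_fraction <- inf_frac
    specs[[i]] <- sp
  }
  specs
}
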