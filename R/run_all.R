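# End-to-end orchestration: simulate a cohort, image it, gate it, run both
# quantification arms, and assemble the cross-modality agreement report.

#' Run configuration
#'
#' Bundles every knob of the end-to-end reproduction: cohort sizes, the
#' master seed, phantom geometry/noise, gating parameters, segmentation
#' parameters and histology slicing. All fields are atomic so the config
#' round-trips through YAML.
#'
#' @param n_ir,n_control cohort sizes (defaults 8 ischemia-reperfusion,
#'   7 control).
#' @param seed master seed; every stochastic stage derives its seed from
#'   it.
#' @param spacing_mm phantom voxel spacing (default 0.077).
#' @param noise_sd_hu per-voxel noise SD (default 30).
#' @param wall_thickness_mm myocardial wall thickness (default 1.0).
#' @param t_first_min time of the first delayed-enhancement acquisition
#'   (default 13 min).
#' @param motion_subject_id IR subject whose delayed image is corrupted
#'   with motion streaks (default 5; NA for none).
#' @param motion_severity streak severity (default 1).
#' @param slice_thickness_mm histology slab thickness (default 1.0).
#' @param pixel_size_mm histology photograph pixel size (default 0.1).
#' @param exhalation_window_fraction respiratory gating window (default
#'   0.3).
#' @param trace_duration_s simulated physiology length per subject; must
#'   comfortably exceed the expected scan time (default 1500).
#' @param simulate_gating whether to simulate per-subject gating
#'   schedules (default TRUE).
#' @param write_volumes whether \code{\link{run_all}} writes the NIfTI
#'   volumes (default FALSE; the per-subject CSV and report are always
#'   written when an output directory is given).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(n_ir = 8L, n_control = 7L, seed = 1L,
                       spacing_mm = 0.077, noise_sd_hu = 30,
                       wall_thickness_mm = 1.0, t_first_min = 13,
                       motion_subject_id = 5L, motion_severity = 1,
                       slice_thickness_mm = 1.0, pixel_size_mm = 0.1,
                       exhalation_window_fraction = 0.3,
                       trace_duration_s = 1500,
                       simulate_gating = TRUE,
                       write_volumes = FALSE) {
  structure(
    list(n_ir = as.integer(n_ir), n_control = as.integer(n_control),
         seed = as.integer(seed), spacing_mm = spacing_mm,
         noise_sd_hu = noise_sd_hu,
         wall_thickness_mm = wall_thickness_mm,
         t_first_min = t_first_min,
         motion_subject_id = motion_subject_id,
         motion_severity = motion_severity,
         slice_thickness_mm = slice_thickness_mm,
         pixel_size_mm = pixel_size_mm,
         exhalation_window_fraction = exhalation_window_fraction,
         trace_duration_s = trace_duration_s,
         simulate_gating = isTRUE(simulate_gating),
         write_volumes = isTRUE(write_volumes)),
    class = "run_config"
  )
}

.stage <- function(name, subject_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for subject %s: %s", name,
                 subject_id, conditionMessage(e)), call. = FALSE))
}

#' End-to-end cohort simulation and quantification
#'
#' Simulates the cohort, generates per-subject gated blood-pool volumes
#' (diastole/systole) and, for IR subjects, a first-acquisition
#' delayed-enhancement volume (one optionally motion-corrupted) plus
#' TTC histology slices; runs the CT and histology quantification arms;
#' and assembles the agreement report over the IR subjects, excluding the
#' motion-corrupted one from the second correlation.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed); NULL writes
#'   nothing.
#' @return list with \code{records} (per-subject data.frame),
#'   \code{report} (an \code{\link{agreement_report}} or NULL),
#'   \code{specs}, and \code{paths} of written files.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  specs <- simulate_cohort(config$n_ir, config$n_control,
                           seed = config$seed,
                           spacing_mm = config$spacing_mm,
                           noise_sd_hu = config$noise_sd_hu,
                           wall_thickness_mm = config$wall_thickness_mm)
  params <- segmentation_params()
  paths <- character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sid <- sp$subject_id
    scan_s <- NA_real_
    if (config$simulate_gating) {
      scan_s <- .stage("gating", sid, {
        set.seed(sp$seed)
        cardiac <- .rtruncnorm1(420, 70, 1, Inf)
        resp <- .rtruncnorm1(108, 17, 1, Inf)
        trace <- simulate_physio(cardiac, resp, jitter_cv = 0.05,
                                 duration_s = config$trace_duration_s,
                                 seed = sp$seed + 1L,
                                 plateau_fraction =
                                   config$exhalation_window_fraction)
        cfg <- gating_config(exhalation_window_fraction =
                               config$exhalation_window_fraction)
        scan_duration(schedule_projections(trace, cfg))
      })
    }
    bp <- .stage("blood-pool imaging", sid, {
      list(dia = build_heart_phantom(sp, "diastole", config$t_first_min,
                                     seed = sp$seed + 2L,
                                     agent = "blood_pool"),
           sys = build_heart_phantom(sp, "systole", config$t_first_min,
                                     seed = sp$seed + 3L,
                                     agent = "blood_pool"))
    })
    ir <- identical(sp$group, "IR")
    delayed <- NULL
    truth_pct <- NA_real_
    if (ir) {
      delayed <- .stage("delayed-enhancement imaging", sid, {
        d <- build_heart_phantom(sp, "diastole", config$t_first_min,
                                 seed = sp$seed + 4L, agent = "iohexol")
        truth_pct <- d$truth$percent_infarct
        if (!is.na(config$motion_subject_id) &&
            sid == config$motion_subject_id)
          d$volume <- add_motion_streaks(d$volume, config$motion_severity,
                                         seed = sp$seed + 5L)
        d
      })
    }
    ct <- .stage("ct quantification", sid,
                 quantify_ct(bp$dia$volume, bp$sys$volume,
                             if (ir) delayed$volume else NULL,
                             params, config$wall_thickness_mm))
    hist_pct <- NA_real_
    if (ir) {
      hist_pct <- .stage("histology quantification", sid, {
        slices <- render_ttc_slices(sp, config$slice_thickness_mm,
                                    config$pixel_size_mm,
                                    seed = sp$seed + 6L)
        percent_infarct_histology(slices)
      })
    }
    if (!is.null(out_dir) && config$write_volumes) {
      for (nm in c("dia", "sys")) {
        p <- file.path(out_dir, sprintf("subject%02d_%s.nii.gz", sid, nm))
        write_volume(bp[[nm]]$volume, p)
        paths <- c(paths, p)
      }
      if (ir) {
        p <- file.path(out_dir, sprintf("subject%02d_delayed.nii.gz", sid))
        write_volume(delayed$volume, p)
        paths <- c(paths, p)
      }
    }
    rows[[i]] <- data.frame(
      subject_id = sid, group = sp$group,
      true_ef = sp$true_ef, true_infarct_pct = truth_pct,
      v_dia_mm3 = ct$v_dia_mm3, v_sys_mm3 = ct$v_sys_mm3, ef = ct$ef,
      ct_infarct_pct = ct$ct_infarct_pct, hist_infarct_pct = hist_pct,
      scan_time_s = scan_s)
  }
  records <- do.call(rbind, rows)
  report <- NULL
  if (config$n_ir >= 2L) {
    report <- agreement_report(
      records[records$group == "IR", ],
      exclude_ids = if (is.na(config$motion_subject_id)) integer(0)
                    else config$motion_subject_id)
  } else {
    warning("fewer than 2 IR subjects: agreement stage skipped")
  }
  if (!is.null(out_dir)) {
    p_csv <- file.path(out_dir, "subjects.csv")
    write_table(records, p_csv)
    p_cfg <- file.path(out_dir, "run_config.yaml")
    write_run_config(config, p_cfg)
    paths <- c(paths, p_csv, p_cfg)
    if (!is.null(report)) {
      p_json <- file.path(out_dir, "agreement_report.json")
      jsonlite::write_json(unclass(report), p_json, auto_unbox = TRUE,
                           digits = NA)
      paths <- c(paths, p_json)
    }
  }
  list(records = records, report = report, specs = specs, paths = paths)
}
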