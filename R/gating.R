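# Prospective dual cardiorespiratory gating of a step-and-shoot micro-CT.
#
# The scanner fires one 15 ms exposure per accepted trigger: the trigger
# must fall a fixed delay after an R-wave (0 ms ~ diastole, 55 ms ~ systole
# in the mouse), the whole exposure must sit inside the end-exhalation
# plateau of the respiratory cycle, and the detector needs a full frame
# period (1 s at 1 Hz) between exposures for readout and gantry stepping.

#' Simulate ECG and respiration traces
#'
#' R-R intervals and respiratory cycle lengths are drawn independently as
#' Normal(60/rate, jitter_cv * 60/rate), truncated positive. Each
#' respiratory cycle starts with an end-exhalation plateau (phase 0)
#' occupying \code{plateau_fraction} of its length, followed by a
#' half-sine breath reaching phase 1 at peak inhalation. The trace starts
#' on an R-wave and a cycle boundary at t = 0.
#'
#' @param cardiac_bpm,resp_bpm mean rates in beats/breaths per minute.
#' @param jitter_cv coefficient of variation of cycle lengths (>= 0).
#' @param duration_s trace length in seconds; must cover at least one
#'   cardiac and one respiratory cycle.
#' @param seed integer seed.
#' @param plateau_fraction fraction of each respiratory cycle spent at the
#'   end-exhalation plateau (default 0.3).
#' @param sample_hz sampling rate of the stored respiratory waveform.
#' @return object of class \code{physio_trace} with fields
#'   \code{r_wave_times_s}, \code{resp_cycle_starts_s},
#'   \code{plateau_fraction}, \code{resp_phase} (sampled waveform),
#'   \code{sample_period_s}, \code{cardiac_bpm_mean},
#'   \code{resp_bpm_mean}, \code{duration_s}.
#' @export
simulate_physio <- function(cardiac_bpm, resp_bpm, jitter_cv = 0.05,
                            duration_s = 60, seed = 1L,
                            plateau_fraction = 0.3, sample_hz = 200) {
  if (cardiac_bpm <= 0 || resp_bpm <= 0) stop("rates must be > 0")
  if (jitter_cv < 0) stop("'jitter_cv' must be >= 0")
  if (plateau_fraction <= 0 || plateau_fraction >= 1)
    stop("'plateau_fraction' must lie in (0, 1)")
  rr <- 60 / cardiac_bpm
  resp <- 60 / resp_bpm
  if (duration_s < max(rr, resp))
    stop("'duration_s' too short to contain one full cycle")
  set.seed(seed)
  draw_times <- function(mean_len) {
    n_guess <- ceiling(duration_s / mean_len * 1.5) + 10L
    times <- 0
    repeat {
      ints <- stats::rnorm(n_guess, mean_len, jitter_cv * mean_len)
      ints <- ints[ints > 0]
      times <- c(times, times[length(times)] + cumsum(ints))
      if (times[length(times)] > duration_s) break
    }
    times[times <= duration_s + mean_len]   # keep one boundary past the end
  }
  r_waves <- draw_times(rr)
  cyc <- draw_times(resp)
  t_samp <- seq(0, duration_s, by = 1 / sample_hz)
  structure(
    list(r_wave_times_s = r_waves[r_waves <= duration_s],
         resp_cycle_starts_s = cyc,
         plateau_fraction = plateau_fraction,
         sample_period_s = 1 / sample_hz,
         resp_phase = NULL,
         cardiac_bpm_mean = cardiac_bpm,
         resp_bpm_mean = resp_bpm,
         duration_s = duration_s),
    class = "physio_trace"
  ) -> tr
  tr$resp_phase <- resp_phase_at(tr, t_samp)
  tr
}

# position within the respiratory cycle, as (u in [0,1), cycle length)
.resp_u <- function(trace, t) {
  idx <- findInterval(t, trace$resp_cycle_starts_s,
                      rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx >= length(trace$resp_cycle_starts_s)] <-
    length(trace$resp_cycle_starts_s) - 1L
  start <- trace$resp_cycle_starts_s[idx]
  len <- trace$resp_cycle_starts_s[idx + 1L] - start
  list(u = (t - start) / len, len = len, start = start)
}

#' Respiratory phase at arbitrary times
#'
#' Phase 0 is the end-exhalation plateau; 1 is peak inhalation.
#'
#' @param trace a \code{physio_trace}.
#' @param t numeric vector of times in seconds.
#' @return numeric vector of phases in [0, 1].
#' @export
resp_phase_at <- function(trace, t) {
  ru <- .resp_u(trace, t)
  p <- trace$plateau_fraction
  phase <- numeric(length(t))
  breathing <- ru$u >= p
  phase[breathing] <- sin(pi * (ru$u[breathing] - p) / (1 - p))
  pmin(1, pmax(0, phase))
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("<physio_trace> %.0f s | %d R-waves (~%.0f bpm) | %d resp cycles (~%.0f bpm)\n",
              x$duration_s, length(x$r_wave_times_s), x$cardiac_bpm_mean,
              length(x$resp_cycle_starts_s) - 1L, x$resp_bpm_mean))
  invisible(x)
}

#' Gating configuration
#'
#' @param r_delay_ms delay of the exposure after the R-wave, in ms
#'   (0 = diastole, 55 = systole).
#' @param exposure_ms x-ray exposure duration (default 15 ms).
#' @param n_projections number of projections (default 286).
#' @param arc_deg total gantry arc (default 200 degrees).
#' @param frame_rate_hz fixed detector frame rate (default 1 Hz); one
#'   frame period must elapse between consecutive triggers.
#' @param exhalation_window_fraction fraction of the respiratory cycle
#'   accepted as end exhalation (default 0.3).
#' @return object of class \code{gating_config}.
#' @export
gating_config <- function(r_delay_ms = 0, exposure_ms = 15,
                          n_projections = 286L, arc_deg = 200,
                          frame_rate_hz = 1,
                          exhalation_window_fraction = 0.3) {
  if (n_projections < 1L) stop("'n_projections' must be >= 1")
  if (arc_deg <= 0 || arc_deg > 360) stop("'arc_deg' must lie in (0, 360]")
  if (frame_rate_hz <= 0) stop("'frame_rate_hz' must be > 0")
  if (exposure_ms >= 1000 / frame_rate_hz)
    stop("'exposure_ms' must be shorter than the frame period")
  if (exhalation_window_fraction <= 0 || exhalation_window_fraction > 1)
    stop("'exhalation_window_fraction' must lie in (0, 1]")
  if (r_delay_ms < 0) stop("'r_delay_ms' must be >= 0")
  structure(
    list(r_delay_ms = r_delay_ms, exposure_ms = exposure_ms,
         n_projections = as.integer(n_projections), arc_deg = arc_deg,
         frame_rate_hz = frame_rate_hz,
         exhalation_window_fraction = exhalation_window_fraction),
    class = "gating_config"
  )
}

#' Evenly spaced gantry angles
#'
#' @param n number of projections (>= 2).
#' @param arc_deg total arc in degrees.
#' @return numeric vector of length \code{n} from 0 to \code{arc_deg}
#'   inclusive (step \code{arc_deg / (n - 1)}).
#' @export
projection_angles <- function(n, arc_deg) {
  if (n < 2L) stop("'n' must be >= 2")
  seq(0, arc_deg, length.out = n)
}

#' Compute the prospectively gated projection schedule
#'
#' Walks the trace's R-waves in time order. A candidate trigger at
#' \code{R + r_delay_ms} fires iff (a) the whole exposure lies inside the
#' end-exhalation window of its respiratory cycle and (b) at least one
#' detector frame period has elapsed since the previous trigger. Stops
#' after \code{n_projections} triggers; errors (reporting the count
#' obtained) if the trace runs out first.
#'
#' @param trace a \code{physio_trace}.
#' @param config a \code{\link{gating_config}}.
#' @return object of class \code{gating_schedule}: \code{trigger_times_s},
#'   \code{angles_deg}, \code{total_time_s} (last trigger + one readout
#'   period), \code{n_rejected_resp}, \code{n_rejected_frame}.
#' @export
schedule_projections <- function(trace, config) {
  stopifnot(inherits(trace, "physio_trace"), inherits(config, "gating_config"))
  tol <- 1e-9
  period <- 1 / config$frame_rate_hz
  expo <- config$exposure_ms / 1000
  cand <- trace$r_wave_times_s + config$r_delay_ms / 1000
  cand <- cand[cand + expo <= trace$duration_s]
  wf <- config$exhalation_window_fraction
  ru1 <- .resp_u(trace, cand)
  ru2 <- .resp_u(trace, cand + expo)
  same_cycle <- ru1$start == ru2$start
  # the whole exposure must sit where the respiratory position is inside
  # the window; a full-cycle window (wf = 1) accepts everything, including
  # exposures spanning a cycle boundary
  in_window <- ru1$u <= wf + tol & ru2$u <= wf + tol &
    (same_cycle | wf >= 1 - tol)
  n_rej_resp <- sum(!in_window)
  valid <- cand[in_window]
  triggers <- numeric(config$n_projections)
  n_got <- 0L
  n_rej_frame <- 0L
  prev <- -Inf
  for (t in valid) {
    if (t + tol >= prev + period) {
      n_got <- n_got + 1L
      triggers[n_got] <- t
      prev <- t
      if (n_got == config$n_projections) break
    } else {
      n_rej_frame <- n_rej_frame + 1L
    }
  }
  if (n_got < config$n_projections)
    stop(errorCondition(
      sprintf("trace exhausted after %d of %d triggers; extend the trace",
              n_got, config$n_projections),
      n_triggers = n_got,
      class = c("insufficient_trace_error", "error", "condition")))
  structure(
    list(trigger_times_s = triggers,
         angles_deg = projection_angles(config$n_projections, config$arc_deg),
         total_time_s = triggers[n_got] + period,
         n_rejected_resp = n_rej_resp,
         n_rejected_frame = n_rej_frame,
         config = config),
    class = "gating_schedule"
  )
}

#' @export
print.gating_schedule <- function(x, ...) {
  cat(sprintf("<gating_schedule> %d projections over %.0f deg | total %.1f s\n",
              length(x$trigger_times_s), x$config$arc_deg, x$total_time_s))
  cat(sprintf("  rejected: %d (respiratory window), %d (detector readout)\n",
              x$n_rejected_resp, x$n_rejected_frame))
  invisible(x)
}

#' Total scan duration of a schedule
#'
#' @param schedule a \code{gating_schedule}.
#' @return total scan time in seconds (last trigger plus one readout
#'   period).
#' @export
scan_duration <- function(schedule) {
  stopifnot(inherits(schedule, "gating_schedule"))
  if (length(schedule$trigger_times_s) == 0L)
    stop("empty schedule has no duration")
  schedule$total_time_s
}
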