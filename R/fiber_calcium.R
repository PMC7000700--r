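#' Rhod-5N calibration parameters
#'
#' The low-affinity calcium indicator rhod-5N trapped in the sealed
#' t-system reports [Ca2+] through
#' \eqn{[Ca^{2+}] = K_d (F - F_{min}) / (F_{max} - F)}. The dye's calcium
#' dissociation constant is 0.8 mM; `f_min` and `f_max` are the per-fiber
#' fluorescence anchors (calcium-free and saturating).
#'
#' @param kd Dissociation constant, mM (default 0.8).
#' @param f_min,f_max Fluorescence anchors, a.u. (`f_max > f_min`).
#' @return A `calibration_params` list.
#' @export
calibration_params <- function(kd = 0.8, f_min = 0, f_max = 1) {
  if (kd <= 0) stop("`kd` must be positive")
  if (f_max <= f_min) stop("`f_max` must exceed `f_min`")
  structure(list(kd = kd, f_min = f_min, f_max = f_max),
            class = "calibration_params")
}

#' Convert rhod-5N fluorescence to t-system calcium
#'
#' \eqn{[Ca^{2+}]_{t\text{-}sys} = K_d (F - F_{min}) / (F_{max} - F)},
#' monotone increasing in F on `[f_min, f_max)`. At the half-saturation
#' fluorescence `(f_min + f_max) / 2` the conversion returns exactly `kd`.
#'
#' @param f Fluorescence (a.u.), `f_min <= f < f_max`. Vectorized.
#' @param params A [calibration_params()].
#' @return Calcium concentration in the units of `params$kd` (mM).
#' @examples
#' p <- calibration_params(kd = 0.8, f_min = 0.1, f_max = 2)
#' calibrate_ca((p$f_min + p$f_max) / 2, p)  # 0.8 mM
#' @export
calibrate_ca <- function(f, params) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(f < params$f_min))
    stop("fluorescence below f_min: outside the calibrated range")
  if (any(f >= params$f_max))
    stop("fluorescence at or above f_max: indicator saturated")
  params$kd * (f - params$f_min) / (params$f_max - f)
}

#' Inverse calibration: calcium to rhod-5N fluorescence
#'
#' @param ca Calcium concentration (>= 0), units of `params$kd`. Vectorized.
#' @param params A [calibration_params()].
#' @return Fluorescence in a.u.; composes with [calibrate_ca()] to identity.
#' @export
ca_to_fluorescence <- function(ca, params) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(ca < 0)) stop("calcium concentration must be non-negative")
  (params$f_max * ca + params$f_min * params$kd) / (params$kd + ca)
}

#' Extract a plateau steady state after a solution change
#'
#' The steady state for one inter-event window is the mean of the final
#' fraction (default 20%) of the samples between the chosen event and the
#' next one (or the trace end), with a drift check: if the fitted linear
#' trend over the plateau window projects to a change larger than
#' `drift_tol` times the trace's fluorescence range, the segment has not
#' plateaued and is flagged.
#'
#' @param trace A `fiber_trace` (from [simulate_fiber_trace()] or read from
#'   file) with attribute `events`, or a data.frame `time_s`/`fluorescence`
#'   with an `events` data.frame supplied via the attribute.
#' @param event_index Which solution event's window to analyze.
#' @param plateau_frac Final fraction of the window used (default 0.2).
#' @param drift_tol Drift tolerance as a fraction of the trace range
#'   (default 0.02).
#' @return List: `value` (mean fluorescence), `se`, `n`, `plateau` (logical
#'   drift check), `drift` (projected change over the window), `window`
#'   (start/end times used).
#' @export
extract_steady_state <- function(trace, event_index, plateau_frac = 0.2,
                                 drift_tol = 0.02) {
  events <- attr(trace, "events")
  if (is.null(events)) stop("trace carries no solution-event annotations")
  if (event_index < 1 || event_index > nrow(events))
    stop("no such event")
  t0 <- events$time[event_index]
  t1 <- if (event_index < nrow(events)) events$time[event_index + 1]
        else max(trace$time_s) + 1e-9
  seg <- trace[trace$time_s >= t0 & trace$time_s < t1, ]
  if (nrow(seg) < 10) stop("inter-event window too short (< 10 samples)")

  n_win <- max(3L, ceiling(nrow(seg) * plateau_frac))
  win <- utils::tail(seg, n_win)
  value <- mean(win$fluorescence)
  se <- stats::sd(win$fluorescence) / sqrt(n_win)

  slope <- stats::coef(stats::lm(fluorescence ~ time_s, data = win))[[2]]
  span <- diff(range(win$time_s))
  rng <- diff(range(trace$fluorescence))
  drift <- abs(slope) * span
  plateau <- rng == 0 || drift <= drift_tol * rng
  list(value = value, se = se, n = n_win, plateau = plateau, drift = drift,
       window = c(start = min(win$time_s), end = max(win$time_s)))
}

#' Tetracaine-referenced RyR leak metric
#'
#' Places a drug steady state on the scale defined by the no-drug control
#' (full t-system uptake, leak fraction 1) and the 1 mM tetracaine level
#' (RyR fully blocked, leak fraction 0):
#' `(ss_drug - ss_tetracaine) / (ss_control - ss_tetracaine)`. Values below
#' the tetracaine floor are kept (negative fraction) and flagged
#' `beyond_tetracaine`, indicating an off-target effect on t-system calcium
#' handling.
#'
#' @param ss_drug Steady-state t-system calcium with the drug (mM).
#' @param ss_control No-drug control steady state (mM).
#' @param ss_tetracaine Tetracaine (RyR-blocked) steady state
#'   (mM, < `ss_control`).
#' @return A `leak_result` list: the three steady states, `leak_fraction`,
#'   `beyond_tetracaine`.
#' @examples
#' leak_metric(0.65, ss_control = 1.0, ss_tetracaine = 0.3)
#' @export
leak_metric <- function(ss_drug, ss_control, ss_tetracaine) {
  if (ss_control <= ss_tetracaine)
    stop("ss_control must exceed ss_tetracaine")
  lf <- (ss_drug - ss_tetracaine) / (ss_control - ss_tetracaine)
  structure(list(ss_drug = ss_drug, ss_control = ss_control,
                 ss_tetracaine = ss_tetracaine, leak_fraction = lf,
                 beyond_tetracaine = lf < 0),
            class = "leak_result")
}

#' Analyze electrically evoked calcium transients
#'
#' Per-stimulus peak analysis of a line-averaged F/F0 trace under field
#' stimulation: for each stimulus, the baseline is the mean F/F0 over the
#' `baseline_window` before the stimulus and the peak is the maximum over
#' the `peak_window` after it; the amplitude is their difference. Reports
#' the mean amplitude and, when a control amplitude is supplied, the
#' percent of control.
#'
#' @param trace Data.frame with `time_s` and `ff0`.
#' @param stim_times Stimulus times (s), all within the trace.
#' @param peak_window Post-stimulus search window, s (default 0.1).
#' @param baseline_window Pre-stimulus baseline window, s (default 0.2).
#' @param control_amplitude Optional mean amplitude of a DMSO control train.
#' @return A `transient_result` list: `amplitudes` (per stimulus),
#'   `baselines`, `mean_amplitude`, `se_amplitude`, `percent_of_control`.
#' @export
analyze_transients <- function(trace, stim_times, peak_window = 0.1,
                               baseline_window = 0.2,
                               control_amplitude = NULL) {
  stopifnot(all(c("time_s", "ff0") %in% names(trace)),
            length(stim_times) >= 1)
  dt <- stats::median(diff(trace$time_s))
  if (dt > 0.010)
    stop("sampling interval exceeds 10 ms; too coarse for peak analysis")
  if (any(stim_times < min(trace$time_s) | stim_times > max(trace$time_s)))
    stop("stimulus outside the trace")

  res <- vapply(stim_times, function(ts) {
    pre <- trace$ff0[trace$time_s >= ts - baseline_window & trace$time_s < ts]
    post <- trace$ff0[trace$time_s > ts & trace$time_s <= ts + peak_window]
    if (length(pre) == 0 || length(post) == 0)
      stop("stimulus too close to the trace edge")
    c(baseline = mean(pre), amplitude = max(post) - mean(pre))
  }, c(baseline = 0, amplitude = 0))

  amps <- res["amplitude", ]
  out <- list(amplitudes = unname(amps), baselines = unname(res["baseline", ]),
              mean_amplitude = mean(amps),
              se_amplitude = stats::sd(amps) / sqrt(length(amps)),
              percent_of_control = if (is.null(control_amplitude)) NA_real_
                                   else 100 * mean(amps) / control_amplitude)
  structure(out, class = "transient_result")
}
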