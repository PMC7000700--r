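#' Configuration for a simulated FLT-FRET screen
#'
#' Bundles the study conditions of a simulated primary screen: the number of
#' runs, the control E/E0 distribution, the compound library and its true
#' effects, and the fluorophore/lifetime parameters. Defaults reproduce the
#' screen conditions: three runs of a 1536-well plate holding the 1280-compound
#' LOPAC library with 256 DMSO control wells; the compound-well E/E0
#' distribution is a narrow Gaussian centered slightly above the DMSO mean
#' (mu = 1.004, sigma = 0.016).
#'
#' DMSO wells draw their E/E0 factor around 1 (so control E/E0 averages 1 by
#' construction after normalization), while compound wells draw around
#' `control_mu` plus their true effect: `control_mu` is the library-wide
#' E/E0 mean relative to the DMSO controls.
#'
#' @param n_runs Number of screen runs (default 3).
#' @param control_mu Compound-well E/E0 mean relative to DMSO (default 1.004).
#' @param control_sigma E/E0 SD (default 0.016; must be >= 0, > 0 for a
#'   realistic screen).
#' @param effect_table Data.frame of true effects: columns `compound_id`,
#'   `effect` (signed E/E0 shift), optional `runs_active` (comma-separated run
#'   indices the effect applies in; `NA` = all runs). Compounds absent from
#'   the table have zero effect. `NULL` means a null library.
#' @param donor_tau Donor-only lifetime in ns (default 4.0).
#' @param fret_E_baseline Baseline FRET efficiency E0 with the sub-saturating
#'   acceptor (default 0.2, in `[0, 1)`).
#' @param donor_cv Relative well-to-well SD of donor-only lifetimes
#'   (default 0.005).
#' @param intensity_mu,intensity_cv Mean and relative SD of the unlabeled
#'   plate's integrated spectral intensity (a.u.).
#' @param donor_only_effects Named numeric: per-compound donor-only lifetime
#'   shift, in units of the donor-only control SD (artifact spikes).
#' @param intensity_effects Named numeric: per-compound unlabeled-intensity
#'   shift in control-SD units.
#' @param photons_per_well Total photon budget per well for the optional
#'   waveform-level simulation (default 1e5).
#' @param read_time Read time recorded in the plate tables, minutes post
#'   compound exposure (default 120: hit effects are largest at the 2-h read).
#' @param seed Integer seed driving all draws.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_runs = 3, control_mu = 1.004,
                              control_sigma = 0.016, effect_table = NULL,
                              donor_tau = 4.0, fret_E_baseline = 0.2,
                              donor_cv = 0.005, intensity_mu = 1000,
                              intensity_cv = 0.01,
                              donor_only_effects = NULL,
                              intensity_effects = NULL,
                              photons_per_well = 1e5, read_time = 120,
                              seed = 1L) {
  stopifnot(n_runs >= 1, control_sigma >= 0,
            fret_E_baseline >= 0, fret_E_baseline < 1,
            donor_tau > 0, donor_cv >= 0, photons_per_well > 0)
  if (!is.null(effect_table)) {
    stopifnot(is.data.frame(effect_table),
              all(c("compound_id", "effect") %in% names(effect_table)))
    if (is.null(effect_table$runs_active))
      effect_table$runs_active <- NA_character_
  }
  structure(list(
    n_runs = n_runs, control_mu = control_mu, control_sigma = control_sigma,
    effect_table = effect_table, donor_tau = donor_tau,
    fret_E_baseline = fret_E_baseline, donor_cv = donor_cv,
    intensity_mu = intensity_mu, intensity_cv = intensity_cv,
    donor_only_effects = donor_only_effects,
    intensity_effects = intensity_effects,
    photons_per_well = photons_per_well, read_time = read_time,
    seed = as.integer(seed)
  ), class = "screen_sim_config")
}

#' Demonstration effect table: 17 strong and 5 marginal modulators
#'
#' Ships the default screen scenario: 17 strong modulators whose E/E0 shift
#' (10-16 control SDs, both FRET-increasing and -decreasing) makes them hits
#' in every run, and 5 marginal modulators that carry a 7-SD effect in
#' exactly two of the three runs, modeling compounds with inconsistent
#' activity. Mirrors a screen outcome of 17 all-run hits and 22 compounds
#' hitting in at least two runs.
#'
#' @param control_sigma The control E/E0 SD the shifts are scaled by.
#' @return Effect table for [screen_sim_config()].
#' @export
demo_effect_table <- function(control_sigma = 0.016) {
  strong_id <- sprintf("LOPAC-%04d", seq(60, 1020, by = 60))  # 17 compounds
  strong_sd <- rep(c(-16, -13, -10, 12, 15), length.out = 17)
  marginal_id <- sprintf("LOPAC-%04d", c(111, 333, 555, 777, 999))
  marginal_sd <- c(-7, 7, -7, 7, -7)
  marginal_runs <- c("1,2", "2,3", "1,3", "1,2", "2,3")
  data.frame(
    compound_id = c(strong_id, marginal_id),
    effect = c(strong_sd, marginal_sd) * control_sigma,
    runs_active = c(rep(NA_character_, 17), marginal_runs),
    class = c(rep("strong", 17), rep("marginal", 5)),
    stringsAsFactors = FALSE
  )
}

effect_active <- function(runs_active, run) {
  if (is.na(runs_active)) return(TRUE)
  run %in% as.integer(strsplit(runs_active, ",")[[1]])
}

#' Simulate a multi-run FLT-FRET screen
#'
#' Emits long-format plate tables for each run: a donor-acceptor plate, a
#' donor-only plate, and an unlabeled plate sharing the layout. Compound-well
#' E/E0 is a control draw plus the compound's true effect; per-well
#' donor-acceptor lifetimes derive from E via tau_DA = tau_D (1 - E).
#' Output is reproducible under the config seed.
#'
#' @param config A [screen_sim_config()].
#' @param layout A [plate_layout_1536()] (default layout).
#' @return A `screen_sim` list: `plates` (one long data.frame across runs with
#'   columns `plate_id`, `run_id`, `read_time_min`, `well`, `row`, `col`,
#'   `sample_type`, `compound_id`, `tau_ns`, `integrated_intensity`), `truth`
#'   (per-compound true effects), `layout`, `config`.
#' @export
simulate_screen <- function(config, layout = plate_layout_1536()) {
  stopifnot(inherits(config, "screen_sim_config"))
  comp_wells <- layout[layout$role == "compound", ]
  ctrl_wells <- layout[layout$role == "control", ]
  n_comp <- nrow(comp_wells)
  compound_ids <- sprintf("LOPAC-%04d", seq_len(n_comp))

  eff <- config$effect_table
  if (!is.null(eff) && !all(eff$compound_id %in% compound_ids))
    stop("effect_table contains compound_id values not in the library")
  effect_of <- stats::setNames(rep(0, n_comp), compound_ids)
  runs_of <- stats::setNames(rep(NA_character_, n_comp), compound_ids)
  if (!is.null(eff)) {
    effect_of[eff$compound_id] <- eff$effect
    runs_of[eff$compound_id] <- eff$runs_active
  }

  sd_shift <- function(table, ids) {
    out <- rep(0, length(ids))
    if (!is.null(table)) {
      hitidx <- match(names(table), ids)
      if (anyNA(hitidx))
        stop("artifact effect names not in the library")
      out[hitidx] <- table
    }
    out
  }
  don_shift <- sd_shift(config$donor_only_effects, compound_ids)
  int_shift <- sd_shift(config$intensity_effects, compound_ids)

  # Effect-table compounds are genuine FRET modulators, artifact-free by
  # construction: their companion-plate noise draws are truncated well inside the
  # false-hit filter band (|z| <= 2.5) so chance draws cannot mimic an artifact.
  # Real companion artifacts are specified via donor_only_effects /
  # intensity_effects instead.
  spiked <- compound_ids %in% if (is.null(eff)) character(0) else eff$compound_id
  trunc_z <- function(n) {
    stats::qnorm(stats::runif(n, stats::pnorm(-2.5), stats::pnorm(2.5)))
  }

  runs <- with_seed(config$seed, lapply(seq_len(config$n_runs), function(r) {
    active <- vapply(runs_of, effect_active, logical(1), run = r)
    eff_r <- ifelse(active, effect_of, 0)

    # donor-acceptor plate: E/E0 factor -> E -> tau_DA
    ratio_comp <- stats::rnorm(n_comp, config$control_mu,
                               config$control_sigma) + eff_r
    ratio_ctrl <- stats::rnorm(nrow(ctrl_wells), 1, config$control_sigma)
    E_comp <- config$fret_E_baseline * ratio_comp
    E_ctrl <- config$fret_E_baseline * ratio_ctrl
    tau_da <- config$donor_tau * (1 - c(E_comp, E_ctrl))

    # donor-only companion plate (lifetime noise + artifact spikes)
    don_sd <- config$donor_tau * config$donor_cv
    zc <- stats::rnorm(n_comp)
    zc[spiked] <- trunc_z(sum(spiked))
    tau_don_comp <- config$donor_tau + zc * don_sd + don_shift * don_sd
    tau_don_ctrl <- stats::rnorm(nrow(ctrl_wells), config$donor_tau, don_sd)

    # unlabeled companion plate (integrated spectral intensity)
    int_sd <- config$intensity_mu * config$intensity_cv
    zi <- stats::rnorm(n_comp)
    zi[spiked] <- trunc_z(sum(spiked))
    int_comp <- config$intensity_mu + zi * int_sd + int_shift * int_sd
    int_ctrl <- stats::rnorm(nrow(ctrl_wells), config$intensity_mu, int_sd)

    one_plate <- function(sample_type, tau_comp, tau_ctrl, i_comp, i_ctrl) {
      rbind(
        data.frame(well = comp_wells$well, row = comp_wells$row,
                   col = comp_wells$col, sample_type = sample_type,
                   compound_id = compound_ids, tau_ns = tau_comp,
                   integrated_intensity = i_comp),
        data.frame(well = ctrl_wells$well, row = ctrl_wells$row,
                   col = ctrl_wells$col, sample_type = sample_type,
                   compound_id = "DMSO", tau_ns = tau_ctrl,
                   integrated_intensity = i_ctrl)
      )
    }
    plate <- rbind(
      one_plate("donor_acceptor", tau_da[seq_len(n_comp)],
                tau_da[-seq_len(n_comp)],
                stats::rnorm(n_comp, config$intensity_mu, int_sd),
                stats::rnorm(nrow(ctrl_wells), config$intensity_mu, int_sd)),
      one_plate("donor_only", tau_don_comp, tau_don_ctrl,
                stats::rnorm(n_comp, config$intensity_mu, int_sd),
                stats::rnorm(nrow(ctrl_wells), config$intensity_mu, int_sd)),
      one_plate("unlabeled", rep(NA_real_, n_comp),
                rep(NA_real_, nrow(ctrl_wells)), int_comp, int_ctrl)
    )
    plate$run_id <- r
    plate$plate_id <- sprintf("run%d_%s", r, plate$sample_type)
    plate$read_time_min <- config$read_time
    plate[, c("plate_id", "run_id", "read_time_min", "well", "row", "col",
              "sample_type", "compound_id", "tau_ns", "integrated_intensity")]
  }))

  truth <- data.frame(compound_id = compound_ids, effect = unname(effect_of),
                      runs_active = unname(runs_of))
  structure(list(plates = do.call(rbind, runs), truth = truth,
                 layout = layout, config = config),
            class = "screen_sim")
}

#' Simulate DMSO vs suramin Z-prime QC plates
#'
#' Donor-acceptor lifetimes for control (DMSO) wells at the baseline FRET
#' level and for reference wells saturated with suramin (which abolishes
#' FRET, so tau_DA = tau_D), each with the stated well-to-well lifetime CV.
#'
#' @param n_wells Wells per group (default 128).
#' @param donor_tau Donor lifetime, ns.
#' @param fret_E_baseline Baseline FRET efficiency of the DMSO wells.
#' @param lifetime_cv Relative well-to-well lifetime SD (default 0.005).
#' @param seed Integer seed.
#' @return List of numeric vectors `dmso_taus` and `suramin_taus` (ns).
#' @export
simulate_zprime_plates <- function(n_wells = 128, donor_tau = 4.0,
                                   fret_E_baseline = 0.2,
                                   lifetime_cv = 0.005, seed = 1L) {
  stopifnot(n_wells >= 2, lifetime_cv >= 0)
  with_seed(seed, {
    tau0 <- donor_tau * (1 - fret_E_baseline)
    list(
      dmso_taus = stats::rnorm(n_wells, tau0, tau0 * lifetime_cv),
      suramin_taus = stats::rnorm(n_wells, donor_tau, donor_tau * lifetime_cv)
    )
  })
}

#' Simulate a replicated dose-response series
#'
#' Replicate responses are the Hill curve evaluated at each concentration
#' plus independent Gaussian noise. Metadata (compound, assay, isoform,
#' redox, free calcium) is carried through to the output table.
#'
#' @param concentrations Positive, sorted concentrations (uM).
#' @param ic50 Generating IC50 (uM).
#' @param n_replicates Replicates per concentration (default 4).
#' @param noise_sd Gaussian response noise SD (>= 0; default 0.03).
#' @param bottom,top Lower/upper response asymptotes (defaults 0, 1).
#' @param hill_coefficient Hill slope (default 1).
#' @param compound_id,assay,isoform,redox,free_ca_nM Metadata columns.
#' @param seed Integer seed.
#' @return A `dose_response_series` data.frame: `compound_id`, `assay`,
#'   `isoform`, `redox`, `free_ca_nM`, `conc_uM`, `replicate`, `response`,
#'   with the generating parameters stored as attribute `truth`.
#' @export
simulate_dose_response <- function(concentrations, ic50, n_replicates = 4,
                                   noise_sd = 0.03, bottom = 0, top = 1,
                                   hill_coefficient = 1,
                                   compound_id = "suramin", assay = "fret",
                                   isoform = "RyR1", redox = "GSH",
                                   free_ca_nM = 30, seed = 1L) {
  if (length(concentrations) == 0) stop("`concentrations` must be non-empty")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be sorted and distinct")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (ic50 <= 0) stop("`ic50` must be positive")
  stopifnot(n_replicates >= 1)

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      conc_uM = concentrations, KEEP.OUT.ATTRS = FALSE)
  mu <- hill_response(grid$conc_uM, bottom, top, ic50, hill_coefficient)
  resp <- with_seed(seed, mu + stats::rnorm(nrow(grid), 0, noise_sd))
  out <- data.frame(compound_id = compound_id, assay = assay,
                    isoform = isoform, redox = redox,
                    free_ca_nM = free_ca_nM, conc_uM = grid$conc_uM,
                    replicate = grid$replicate, response = resp)
  structure(out,
            truth = list(bottom = bottom, top = top, ic50 = ic50,
                         hill_coefficient = hill_coefficient,
                         noise_sd = noise_sd),
            class = c("dose_response_series", "data.frame"))
}

#' Configuration for a simulated skinned-fiber t-system trace
#'
#' Steady-state t-system calcium levels (mM) bounded by the no-drug control
#' ceiling (full t-system uptake driven by RyR leak) and the 1 mM tetracaine
#' floor (RyR fully blocked); caffeine depletes the t-system below the floor
#' via store-operated calcium entry. Kinetics are a single-exponential
#' approach to each plateau. Fluorescence is generated by inverting the
#' rhod-5N calibration, so [calibrate_ca()] recovers the calcium level
#' exactly in the noiseless case.
#'
#' @param ss_control Steady-state t-system calcium with functional RyR leak
#'   (mM, default 1.0).
#' @param ss_tetracaine Steady state with RyR blocked (mM, default 0.3;
#'   must be below `ss_control`).
#' @param ss_caffeine Depleted level under 30 mM caffeine (mM, default 0.02).
#' @param drug_effects Named list mapping a `"compound@dose"` event label to
#'   its steady-state level (mM).
#' @param approach_tau Exponential approach time constant (s, > 0).
#' @param noise_sd Fluorescence noise SD (a.u.).
#' @param kd Rhod-5N calcium dissociation constant (mM, default 0.8).
#' @param f_min,f_max Calibration anchors (a.u.).
#' @param seed Integer seed.
#' @return A `fiber_sim_config` list.
#' @export
fiber_sim_config <- function(ss_control = 1.0, ss_tetracaine = 0.3,
                             ss_caffeine = 0.02, drug_effects = list(),
                             approach_tau = 20, noise_sd = 0, kd = 0.8,
                             f_min = 0.1, f_max = 2.0, seed = 1L) {
  if (ss_tetracaine >= ss_control)
    stop("ss_tetracaine must be below ss_control")
  if (approach_tau <= 0) stop("approach_tau must be positive")
  stopifnot(noise_sd >= 0, kd > 0, f_max > f_min)
  structure(list(ss_control = ss_control, ss_tetracaine = ss_tetracaine,
                 ss_caffeine = ss_caffeine, drug_effects = drug_effects,
                 approach_tau = approach_tau, noise_sd = noise_sd,
                 kd = kd, f_min = f_min, f_max = f_max,
                 seed = as.integer(seed)),
            class = "fiber_sim_config")
}

target_level <- function(label, config) {
  switch(label,
         standard = , washout = config$ss_control,
         tetracaine = config$ss_tetracaine,
         caffeine = config$ss_caffeine,
         {
           lv <- config$drug_effects[[label]]
           if (is.null(lv))
             stop("no steady-state level configured for event label '",
                  label, "'")
           lv
         })
}

#' Simulate a skinned-fiber t-system fluorescence trace
#'
#' Builds a piecewise trace: after each solution-change event the t-system
#' calcium approaches that solution's steady state exponentially, and the
#' calcium level is mapped to rhod-5N fluorescence through the inverse of
#' the calibration equation (plus optional Gaussian noise).
#'
#' @param config A [fiber_sim_config()].
#' @param protocol Data.frame of solution events: `time` (s, ordered,
#'   starting at 0) and `label` (`standard`, `tetracaine`, `caffeine`,
#'   `washout`, or a `"compound@dose"` key of `config$drug_effects`).
#' @param duration Trace length in s (default: last event + 6 approach taus).
#' @param dt Sampling interval in s (default 0.2).
#' @return A `fiber_trace` data.frame (`time_s`, `fluorescence`) with
#'   attributes `events` (the protocol), `calibration`
#'   ([calibration_params()]) and `true_levels` (per-event target, mM).
#' @export
simulate_fiber_trace <- function(config, protocol, duration = NULL, dt = 0.2) {
  stopifnot(inherits(config, "fiber_sim_config"), is.data.frame(protocol),
            all(c("time", "label") %in% names(protocol)), nrow(protocol) >= 1)
  if (is.unsorted(protocol$time, strictly = TRUE))
    stop("protocol events must be strictly time-ordered")
  if (protocol$time[1] != 0) stop("protocol must start with an event at t = 0")
  if (is.null(duration)) duration <- max(protocol$time) + 6 * config$approach_tau
  if (any(protocol$time >= duration))
    stop("protocol events must lie within the trace duration")

  targets <- vapply(protocol$label, target_level, numeric(1), config = config)
  time <- seq(0, duration, by = dt)
  ca <- numeric(length(time))
  level <- targets[1]
  bounds <- c(protocol$time, duration)
  for (i in seq_len(nrow(protocol))) {
    idx <- time >= bounds[i] & time < bounds[i + 1] |
      (i == nrow(protocol) & time == duration)
    tt <- time[idx] - bounds[i]
    ca[idx] <- targets[i] + (level - targets[i]) * exp(-tt / config$approach_tau)
    level <- targets[i] + (level - targets[i]) *
      exp(-(bounds[i + 1] - bounds[i]) / config$approach_tau)
  }

  params <- calibration_params(kd = config$kd, f_min = config$f_min,
                               f_max = config$f_max)
  f <- ca_to_fluorescence(ca, params)
  if (config$noise_sd > 0)
    f <- with_seed(config$seed,
                   f + stats::rnorm(length(f), 0, config$noise_sd))
  structure(data.frame(time_s = time, fluorescence = f),
            events = data.frame(time = protocol$time, label = protocol$label),
            calibration = params,
            true_levels = stats::setNames(targets, protocol$label),
            class = c("fiber_trace", "data.frame"))
}

#' Simulate an electrically evoked calcium-transient train
#'
#' F/F0 transients at a fixed pacing frequency: each stimulus triggers a
#' linear rise over `rise_time` to exactly `amplitude` above baseline,
#' followed by an exponential decay. Sampling at 2 ms emulates line-scan
#' imaging at 2 ms per line.
#'
#' @param n_stim Number of stimuli (default 6).
#' @param amplitude Peak Delta F/F0 per transient.
#' @param baseline Resting F/F0 (default 1).
#' @param period Pacing period in s (default 1: 1 Hz field stimulation).
#' @param rise_time Rise time to peak, s (default 0.006).
#' @param decay_tau Decay time constant, s (default 0.06).
#' @param dt Sampling interval, s (default 0.002).
#' @param pre Pre-train baseline duration, s (default 0.5).
#' @param noise_sd Gaussian F/F0 noise SD.
#' @param seed Integer seed.
#' @return List: `trace` (data.frame `time_s`, `ff0`) and `stim_times` (s).
#' @export
simulate_transient_train <- function(n_stim = 6, amplitude = 0.8,
                                     baseline = 1, period = 1,
                                     rise_time = 0.006, decay_tau = 0.06,
                                     dt = 0.002, pre = 0.5, noise_sd = 0,
                                     seed = 1L) {
  stopifnot(n_stim >= 1, amplitude >= 0, decay_tau > 0, rise_time > 0,
            dt > 0, noise_sd >= 0)
  stim_times <- pre + (seq_len(n_stim) - 1) * period
  time <- seq(0, pre + n_stim * period, by = dt)
  ff0 <- rep(baseline, length(time))
  for (ts in stim_times) {
    rel <- time - ts
    shape <- ifelse(rel < 0, 0,
                    ifelse(rel <= rise_time, rel / rise_time,
                           exp(-(rel - rise_time) / decay_tau)))
    ff0 <- ff0 + amplitude * shape
  }
  if (noise_sd > 0)
    ff0 <- with_seed(seed, ff0 + stats::rnorm(length(ff0), 0, noise_sd))
  list(trace = data.frame(time_s = time, ff0 = ff0), stim_times = stim_times)
}

#' Simulate the decay waveform of one screening well
#'
#' Bridges the screen simulation to the waveform level: emits a
#' Poisson-noised mono-exponential decay whose integrated counts match the
#' config's per-well photon budget, for the given fitted-lifetime ground
#' truth. Fitting these waveforms with [fit_lifetime()] reproduces the
#' plate tables' `tau_ns` values up to shot noise.
#'
#' @param config A [screen_sim_config()] (supplies `photons_per_well`).
#' @param tau True donor lifetime of the well, ns.
#' @param n_bins,bin_width Waveform grid (defaults 512 x 0.05 ns).
#' @param seed Optional seed for the Poisson draw.
#' @param well_id Optional well identifier.
#' @return A `decay_waveform` (see [simulate_decay()]).
#' @export
simulate_well_waveform <- function(config, tau, n_bins = 512,
                                   bin_width = 0.05, seed = NULL,
                                   well_id = NA_character_) {
  stopifnot(inherits(config, "screen_sim_config"), tau > 0)
  amplitude <- config$photons_per_well * bin_width / tau
  simulate_decay(tau, amplitude, background = 0, n_bins = n_bins,
                 bin_width = bin_width, noise = "poisson", seed = seed,
                 well_id = well_id, read_time = config$read_time)
}
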