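test_that("null screen reproduces the control E/E0 distribution", {
  cfg <- screen_sim_config(seed = 3)
  sim <- simulate_screen(cfg)
  pooled <- unlist(lapply(split(sim$plates, sim$plates$run_id), function(run) {
    nr <- normalize_plate(run)
    nr$E_ratio[nr$compound_id != "DMSO"]
  }))
  n <- length(pooled)
  expect_equal(n, 3 * 1280)
  expect_lt(abs(mean(pooled) - 1.004), 3 * 0.016 / sqrt(n) + 3 * 0.016 / sqrt(256 * 3))
  expect_equal(sd(pooled), 0.016, tolerance = 0.05)
})

test_that("degenerate noise gives exact E/E0 values", {
  cfg <- screen_sim_config(control_sigma = 0, control_mu = 1.004,
                           donor_cv = 0, intensity_cv = 0, n_runs = 1,
                           seed = 1)
  nr <- normalize_plate(simulate_screen(cfg)$plates)
  expect_equal(unique(round(nr$E_ratio[nr$compound_id != "DMSO"], 12)), 1.004)
  expect_equal(unique(round(nr$E_ratio[nr$compound_id == "DMSO"], 12)), 1)
})

test_that("screen simulation is bit-identical under a fixed seed", {
  cfg <- screen_sim_config(effect_table = demo_effect_table(), seed = 77)
  expect_identical(simulate_screen(cfg)$plates, simulate_screen(cfg)$plates)
  cfg2 <- screen_sim_config(effect_table = demo_effect_table(), seed = 78)
  expect_false(identical(simulate_screen(cfg)$plates,
                         simulate_screen(cfg2)$plates))
})

test_that("generated E/E0 sample SD converges to control_sigma", {
  # pool 8 independent runs: 10240 compound wells
  cfg <- screen_sim_config(n_runs = 8, seed = 9)
  sim <- simulate_screen(cfg)
  pooled <- unlist(lapply(split(sim$plates, sim$plates$run_id), function(run) {
    nr <- normalize_plate(run)
    nr$E_ratio[nr$compound_id != "DMSO"]
  }))
  expect_gte(length(pooled), 1e4)
  expect_equal(sd(pooled), 0.016, tolerance = 0.05)
})

test_that("spiked compounds are recovered exactly by hit calling", {
  spikes <- sprintf("LOPAC-%04d", seq(25, 500, by = 25))  # 20 compounds
  eff <- data.frame(compound_id = spikes,
                    effect = rep(c(10, -10), 10) * 0.016)
  cfg <- screen_sim_config(n_runs = 1, effect_table = eff, seed = 21)
  run <- simulate_screen(cfg)$plates
  hits <- call_hits(normalize_plate(run), filter_false_hits(run))
  expect_setequal(hits$compound_id[hits$hit], spikes)
})

test_that("effect table keys must match the library", {
  eff <- data.frame(compound_id = "NOT-A-COMPOUND", effect = 0.1)
  cfg <- screen_sim_config(effect_table = eff)
  expect_error(simulate_screen(cfg), "not in the library")
})

test_that("dose-response simulation reproduces the Hill curve", {
  conc <- log_spaced()
  noiseless <- simulate_dose_response(conc, ic50 = 5.9, noise_sd = 0,
                                      isoform = "RyR2", redox = "GSSG")
  expect_equal(noiseless$response,
               hill_response(noiseless$conc_uM, 0, 1, 5.9, 1))
  expect_equal(unique(noiseless$isoform), "RyR2")
  expect_equal(unique(noiseless$redox), "GSSG")
  expect_equal(nrow(noiseless), 8 * 4)

  expect_error(simulate_dose_response(numeric(0), ic50 = 1), "non-empty")
  expect_error(simulate_dose_response(conc, ic50 = 1, noise_sd = -1),
               "non-negative")
  expect_error(simulate_dose_response(rev(conc), ic50 = 1), "sorted")
})

test_that("dose-response refits recover the generating IC50 within fit SE", {
  zs <- vapply(1:21, function(s) {
    ser <- simulate_dose_response(log_spaced(), ic50 = 5.9, seed = 400 + s)
    fit <- fit_hill(ser)
    abs(fit$ic50 - 5.9) / fit$se[["ic50"]]
  }, numeric(1))
  expect_lt(median(zs), 1)
})

test_that("fiber traces plateau at the configured steady states", {
  cfg <- fiber_sim_config(approach_tau = 10)
  prot <- data.frame(time = c(0, 100), label = c("standard", "tetracaine"))
  tr <- simulate_fiber_trace(cfg, prot, duration = 200, dt = 0.1)
  cal <- attr(tr, "calibration")
  ss1 <- extract_steady_state(tr, 1)
  ss2 <- extract_steady_state(tr, 2)
  expect_true(ss1$plateau && ss2$plateau)
  expect_equal(calibrate_ca(ss1$value, cal), cfg$ss_control, tolerance = 0.01)
  expect_equal(calibrate_ca(ss2$value, cal), cfg$ss_tetracaine,
               tolerance = 0.01)
})

test_that("drug washout restores the no-drug control plateau", {
  cfg <- fiber_sim_config(approach_tau = 10,
                          drug_effects = list("myricetin@1" = 0.6))
  prot <- data.frame(time = c(0, 100, 200),
                     label = c("standard", "myricetin@1", "washout"))
  tr <- simulate_fiber_trace(cfg, prot, duration = 320, dt = 0.1)
  cal <- attr(tr, "calibration")
  drug <- calibrate_ca(extract_steady_state(tr, 2)$value, cal)
  back <- calibrate_ca(extract_steady_state(tr, 3)$value, cal)
  expect_equal(drug, 0.6, tolerance = 0.01)
  expect_equal(back, cfg$ss_control, tolerance = 0.01)
})

test_that("leak metric on a simulated drug trace recovers the generating level", {
  lv <- 0.65
  cfg <- fiber_sim_config(approach_tau = 8,
                          drug_effects = list("chloroxine@10" = lv))
  prot <- data.frame(time = c(0, 80, 160),
                     label = c("standard", "chloroxine@10", "tetracaine"))
  tr <- simulate_fiber_trace(cfg, prot, duration = 260, dt = 0.1)
  cal <- attr(tr, "calibration")
  ss <- vapply(1:3, function(i)
    calibrate_ca(extract_steady_state(tr, i)$value, cal), numeric(1))
  lk <- leak_metric(ss[2], ss[1], ss[3])
  truth <- (lv - cfg$ss_tetracaine) / (cfg$ss_control - cfg$ss_tetracaine)
  expect_equal(lk$leak_fraction, truth, tolerance = 0.02)
})

test_that("fiber protocol validation rejects bad event lists", {
  cfg <- fiber_sim_config()
  expect_error(simulate_fiber_trace(
    cfg, data.frame(time = c(0, 50), label = c("standard", "tetracaine")),
    duration = 40), "within the trace duration")
  expect_error(simulate_fiber_trace(
    cfg, data.frame(time = c(10, 0), label = c("standard", "tetracaine"))),
    "time-ordered")
  expect_error(simulate_fiber_trace(
    cfg, data.frame(time = 0, label = "mystery@1")), "no steady-state level")
})

test_that("transient trains have exact peaks and reproducible noise", {
  tt <- simulate_transient_train(n_stim = 4, amplitude = 0.8)
  expect_equal(max(tt$trace$ff0), 1.8, tolerance = 1e-6)
  a <- simulate_transient_train(noise_sd = 0.02, seed = 5)
  b <- simulate_transient_train(noise_sd = 0.02, seed = 5)
  expect_identical(a$trace$ff0, b$trace$ff0)
})

test_that("well waveforms carry the photon budget and refit their lifetime", {
  cfg <- screen_sim_config(photons_per_well = 1e5)
  wf <- simulate_well_waveform(cfg, tau = 3.6, seed = 15)
  expect_equal(sum(wf$counts), 1e5, tolerance = 0.02)
  expect_equal(fit_lifetime(wf)$tau, 3.6, tolerance = 0.02)
})
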