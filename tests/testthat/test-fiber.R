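test_that("rhod-5N calibration has the right anchors and inverse", {
  p <- calibration_params(kd = 0.8, f_min = 0.1, f_max = 2.0)
  expect_equal(calibrate_ca((p$f_min + p$f_max) / 2, p), 0.8)  # midpoint = Kd
  expect_equal(calibrate_ca(p$f_min, p), 0)
  expect_error(calibrate_ca(p$f_max, p), "saturated")
  expect_error(calibrate_ca(p$f_min - 0.01, p), "below")
  expect_error(calibration_params(kd = -1), "positive")
  expect_error(calibration_params(f_min = 2, f_max = 1), "exceed")

  # forward and inverse compose to identity on (f_min, f_max)
  fs <- seq(p$f_min, p$f_max - 1e-6, length.out = 100)
  expect_equal(ca_to_fluorescence(calibrate_ca(fs, p), p), fs,
               tolerance = 1e-9)
  cas <- seq(0, 50, length.out = 100)
  expect_equal(calibrate_ca(ca_to_fluorescence(cas, p), p), cas,
               tolerance = 1e-9)
  # monotone increasing in fluorescence
  expect_true(all(diff(calibrate_ca(fs, p)) > 0))
})

test_that("plateau extraction is exact on constant segments and flags drift", {
  cfg <- fiber_sim_config(approach_tau = 10)
  mk_trace <- function(f, t, events) {
    structure(data.frame(time_s = t, fluorescence = f), events = events,
              class = c("fiber_trace", "data.frame"))
  }
  t <- seq(0, 100, by = 0.5)
  ev <- data.frame(time = 0, label = "standard")
  const <- mk_trace(rep(0.7, length(t)), t, ev)
  ss <- extract_steady_state(const, 1)
  expect_equal(ss$value, 0.7)
  expect_true(ss$plateau)

  # washout step (drug plateau back to control), 5 time constants
  # elapsed: plateau value within 1% of the target level
  cfgd <- fiber_sim_config(approach_tau = 10,
                           drug_effects = list("drug@1" = 0.6))
  tr5 <- simulate_fiber_trace(cfgd, data.frame(time = c(0, 60),
                                               label = c("drug@1", "washout")),
                              duration = 60 + 5 * 10, dt = 0.2)
  cal <- attr(tr5, "calibration")
  ss5 <- extract_steady_state(tr5, 2)
  expect_true(ss5$plateau)
  expect_equal(calibrate_ca(ss5$value, cal), cfgd$ss_control, tolerance = 0.01)

  # only 1 time constant elapsed: still rising, flagged non-plateau
  tr1 <- simulate_fiber_trace(cfg, data.frame(time = c(0, 60),
                                              label = c("caffeine", "standard")),
                              duration = 60 + 10, dt = 0.2)
  expect_false(extract_steady_state(tr1, 2)$plateau)

  short <- mk_trace(rep(1, 5), seq(0, 2, by = 0.5), ev)
  expect_error(extract_steady_state(short, 1), "too short")
  expect_error(extract_steady_state(const, 3), "no such event")
})

test_that("plateau error vanishes as the window grows (noiseless generator)", {
  cfg <- fiber_sim_config(approach_tau = 10)
  errs <- vapply(c(3, 5, 8), function(k) {
    tr <- simulate_fiber_trace(cfg, data.frame(time = c(0, 60),
                                               label = c("caffeine", "standard")),
                               duration = 60 + k * 10, dt = 0.2)
    abs(calibrate_ca(extract_steady_state(tr, 2)$value,
                     attr(tr, "calibration")) - cfg$ss_control)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the leak metric maps its reference levels to 0 and 1 exactly", {
  expect_equal(leak_metric(0.3, 1.0, 0.3)$leak_fraction, 0)
  expect_equal(leak_metric(1.0, 1.0, 0.3)$leak_fraction, 1)
  beyond <- leak_metric(0.25, 1.0, 0.3)
  expect_lt(beyond$leak_fraction, 0)
  expect_true(beyond$beyond_tetracaine)
  expect_false(leak_metric(0.65, 1.0, 0.3)$beyond_tetracaine)
  expect_error(leak_metric(0.5, 0.3, 1.0), "exceed")

  # affine invariance: rescaling all steady states leaves the fraction alone
  lf <- function(a, b) leak_metric(a * 0.65 + b, a * 1.0 + b,
                                   a * 0.3 + b)$leak_fraction
  expect_equal(lf(1, 0), lf(3.7, 0.2))
})

test_that("a monotone decreasing dose series gives monotone leak fractions", {
  levels <- c(0.9, 0.7, 0.5, 0.35)
  cfg <- fiber_sim_config(approach_tau = 8, drug_effects = as.list(
    setNames(levels, paste0("drug@", 1:4))))
  fracs <- vapply(seq_along(levels), function(i) {
    prot <- data.frame(time = c(0, 80, 160),
                       label = c("standard", paste0("drug@", i), "tetracaine"))
    tr <- simulate_fiber_trace(cfg, prot, duration = 260, dt = 0.2)
    cal <- attr(tr, "calibration")
    ss <- vapply(1:3, function(j)
      calibrate_ca(extract_steady_state(tr, j)$value, cal), numeric(1))
    leak_metric(ss[2], ss[1], ss[3])$leak_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})

test_that("transient analysis recovers amplitudes and percent of control", {
  flat <- list(trace = data.frame(time_s = seq(0, 3, by = 0.002), ff0 = 1),
               stim_times = c(0.5, 1.5, 2.5))
  res <- analyze_transients(flat$trace, flat$stim_times)
  expect_equal(res$amplitudes, c(0, 0, 0))

  tt <- simulate_transient_train(n_stim = 6, amplitude = 0.8)
  res2 <- analyze_transients(tt$trace, tt$stim_times)
  expect_equal(res2$mean_amplitude, 0.8, tolerance = 1e-6)

  # drug train at 52% of the control amplitude: ~48% reduction
  drug <- simulate_transient_train(n_stim = 6, amplitude = 0.8 * 0.52,
                                   noise_sd = 0.01, seed = 61)
  res3 <- analyze_transients(drug$trace, drug$stim_times,
                             control_amplitude = res2$mean_amplitude)
  expect_equal(res3$percent_of_control, 52, tolerance = 0.05)
  expect_equal(100 - res3$percent_of_control, 48, tolerance = 2)

  expect_error(analyze_transients(tt$trace, 1e4), "outside")
  coarse <- data.frame(time_s = seq(0, 3, by = 0.05), ff0 = 1)
  expect_error(analyze_transients(coarse, 0.5), "10 ms")
})
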