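test_that("the default 1536-well layout has 1280 compound and 256 control wells", {
  layout <- plate_layout_1536()
  expect_equal(sum(layout$role == "compound"), 1280)
  expect_equal(sum(layout$role == "control"), 256)
  expect_equal(nrow(layout), 1536)
  expect_false(any(duplicated(layout$well)))
  expect_true(all(grepl("^[A-Z]{1,2}[0-9]{2}$", layout$well)))
  expect_error(plate_layout_1536(compound_cols = 1:40, control_cols = 40:48),
               "disjoint")
})

test_that("normalization maps identical wells to E/E0 = 1 and suramin to 0", {
  run <- tiny_run(tau_da_comp = rep(3.2, 10), tau_da_ctrl = rep(3.2, 12))
  nr <- normalize_plate(run)
  expect_equal(attr(nr, "tau_D"), 4)
  expect_equal(unique(nr$E_ratio), 1)

  # a suramin-like compound well with tau_DA = tau_D: E = 0, E/E0 = 0
  run2 <- tiny_run(tau_da_comp = c(4, rep(3.2, 9)), tau_da_ctrl = rep(3.2, 12))
  nr2 <- normalize_plate(run2)
  expect_equal(nr2$E[nr2$compound_id == "CMP-001"], 0)
  expect_equal(nr2$E_ratio[nr2$compound_id == "CMP-001"], 0)

  run3 <- tiny_run(tau_da_comp = rep(3.2, 10), tau_da_ctrl = rep(3.2, 5))
  expect_error(normalize_plate(run3), "fewer than 8")
})

test_that("false-hit filters flag companion-plate deviants and only those", {
  set.seed(30)
  run <- tiny_run(tau_da_comp = rep(3.2, 20), tau_da_ctrl = rep(3.2, 12),
                  tau_don_comp = rnorm(20, 4, 0.02),
                  tau_don_ctrl = rnorm(12, 4, 0.02),
                  int_comp = rnorm(20, 1000, 10),
                  int_ctrl = rnorm(12, 1000, 10))
  base <- filter_false_hits(run)
  expect_false(any(base$flagged[abs(run$tau_ns[run$sample_type ==
    "donor_only"][1:20] - 4) < 0.02]))

  # spike compound 3 by ~10 control SDs on donor-only tau, 5 on intensity
  run$tau_ns[run$sample_type == "donor_only" &
               run$compound_id == "CMP-003"] <- 4 + 10 * 0.02
  run$integrated_intensity[run$sample_type == "unlabeled" &
                             run$compound_id == "CMP-005"] <- 1000 + 10 * 10
  fl <- filter_false_hits(run)
  expect_true(fl$donor_only_artifact[fl$compound_id == "CMP-003"])
  expect_true(fl$intensity_artifact[fl$compound_id == "CMP-005"])
  expect_true(all(fl$flagged[fl$compound_id %in% c("CMP-003", "CMP-005")]))

  expect_error(filter_false_hits(run[run$sample_type != "unlabeled", ]),
               "companion")
})

test_that("null artifact flag rate matches the 3-SD Gaussian tail", {
  cfg <- screen_sim_config(n_runs = 8, seed = 13)
  sim <- simulate_screen(cfg)
  flags <- do.call(rbind, lapply(split(sim$plates, sim$plates$run_id),
                                 filter_false_hits))
  n <- nrow(flags)  # 10240 compound draws per filter
  p <- 2 * pnorm(-3)
  # margin: binomial error plus tail inflation from the per-plate
  # control-SD estimate (256 wells) entering the threshold
  for (rate in c(mean(flags$donor_only_artifact),
                 mean(flags$intensity_artifact))) {
    expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n) + 0.5 * p)
  }
})

test_that("hit calling uses a strict threshold and respects artifact flags", {
  # one compound exactly at 4.0 SD, one just above, one flagged
  # (SD chosen binary-exact so the boundary value is representable)
  s <- 0.015625
  nr <- fake_normalized(c(1 + 4 * s, 1 + 4.01 * s, 1 - 6 * s, 1),
                        ctrl_mean = 1, ctrl_sd = s)
  art <- data.frame(compound_id = "CMP-003", donor_only_artifact = TRUE,
                    intensity_artifact = FALSE, flagged = TRUE)
  hits <- call_hits(nr, art)
  expect_false(hits$hit[hits$compound_id == "CMP-001"])  # boundary: not a hit
  expect_true(hits$hit[hits$compound_id == "CMP-002"])
  expect_false(hits$hit[hits$compound_id == "CMP-003"])  # flagged
  expect_equal(hits$direction[hits$compound_id == "CMP-002"], 1)

  nr0 <- fake_normalized(c(1, 1, 1), ctrl_sd = 0)
  expect_error(call_hits(nr0), "zero")
})

test_that("raising the hit threshold never enlarges the hit set", {
  cfg <- screen_sim_config(effect_table = demo_effect_table(), n_runs = 1,
                           seed = 17)
  run <- simulate_screen(cfg)$plates
  nr <- normalize_plate(run)
  fl <- filter_false_hits(run)
  prev <- NULL
  for (k in c(3, 4, 5, 6)) {
    cur <- call_hits(nr, fl, k_sd = k)
    cur_ids <- cur$compound_id[cur$hit]
    if (!is.null(prev)) expect_true(all(cur_ids %in% prev))
    prev <- cur_ids
  }
})

test_that("artifact-flagged compounds never reach hit or reproducibility lists", {
  eff <- data.frame(compound_id = c("LOPAC-0100", "LOPAC-0200"),
                    effect = c(12, -12) * 0.016)
  cfg <- screen_sim_config(effect_table = eff,
                           donor_only_effects = c("LOPAC-0100" = 10),
                           seed = 23)
  res <- run_screen_pipeline(cfg)
  for (h in res$per_run) {
    expect_false(h$hit[h$compound_id == "LOPAC-0100"])
    expect_true(h$hit[h$compound_id == "LOPAC-0200"])
  }
  rep <- res$reproducible
  expect_false(rep$reproducible_hit[rep$compound_id == "LOPAC-0100"])
  expect_true(rep$reproducible_hit[rep$compound_id == "LOPAC-0200"])
})

test_that("reproducibility requires same-sign hits in enough runs", {
  mk <- function(dirs) {
    data.frame(compound_id = c("A", "B", "C"), E = 0.2, E_ratio = 1,
               delta_in_sd = 5 * dirs, flagged = FALSE, hit = dirs != 0,
               direction = dirs)
  }
  # A: hit in runs 1 and 3; B: opposite signs; C: never
  runs <- list(mk(c(1, 1, 0)), mk(c(0, -1, 0)), mk(c(1, 0, 0)))
  agg <- aggregate_reproducibility(runs)
  expect_true(agg$reproducible_hit[agg$compound_id == "A"])
  expect_false(agg$reproducible_hit[agg$compound_id == "B"])
  expect_false(agg$reproducible_hit[agg$compound_id == "C"])
  expect_equal(agg$direction[agg$compound_id == "A"], 1)

  expect_error(aggregate_reproducibility(runs[1]), "at least 2")
  bad <- runs
  bad[[2]]$compound_id <- c("A", "B", "D")
  expect_error(aggregate_reproducibility(bad), "mismatched")
})

test_that("Z-prime matches arithmetic, limits, and affine invariance", {
  expect_equal(z_prime(c(1, 1, 1), c(2, 2, 2))$z_prime, 1)  # zero-SD limit
  set.seed(8)
  ctrl <- rnorm(200, 0, 0.05); ref <- rnorm(200, 1, 0.05)
  zp <- z_prime(ctrl, ref)
  expect_equal(zp$z_prime,
               1 - 3 * (sd(ctrl) + sd(ref)) / abs(mean(ref) - mean(ctrl)))
  # affine rescaling of all lifetimes leaves Z' unchanged
  expect_equal(z_prime(2.5 * ctrl + 7, 2.5 * ref + 7)$z_prime, zp$z_prime)
  expect_error(z_prime(c(1, 2), c(1.5, 1.5)), "undefined")
})

test_that("simulated DMSO/suramin QC plates reach the reported Z-prime class", {
  qc <- simulate_zprime_plates(n_wells = 128, lifetime_cv = 0.005, seed = 4)
  expect_gt(z_prime(qc$dmso_taus, qc$suramin_taus)$z_prime, 0.8)
})

test_that("Gaussian control fit recovers parameters, robustly under spikes", {
  expect_warning(g0 <- fit_control_gaussian(rep(1.2, 60)), "degenerate")
  expect_equal(g0$mu, 1.2)
  expect_equal(g0$sigma, 0)

  set.seed(14)
  x <- rnorm(3840, 1.004, 0.016)
  g <- fit_control_gaussian(x)
  expect_lt(abs(g$mu - 1.004), 3 * g$se_mu)
  expect_lt(abs(g$sigma - 0.016), 3 * g$se_sigma)

  # 2% large-effect spikes: robust fit keeps sigma within 5%
  xs <- c(x, rnorm(78, 1.004 + 12 * 0.016, 0.016))
  expect_gt(fit_control_gaussian(xs)$sigma, 0.016 * 1.05)
  expect_equal(fit_control_gaussian(xs, robust = TRUE)$sigma, 0.016,
               tolerance = 0.05)

  expect_error(fit_control_gaussian(rnorm(10)), "at least 50")
})

test_that("hit rate is hits over library size", {
  expect_equal(hit_rate(logical(0), 1280), 0)
  expect_equal(hit_rate(rep(c(TRUE, FALSE), c(25, 1255)), 1280), 25 / 1280)
  expect_equal(round(100 * hit_rate(rep(TRUE, 25), 1280), 2), 1.95)
  expect_error(hit_rate(TRUE, 0), "positive")
})
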