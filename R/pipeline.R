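#' Read a long-format plate table
#'
#' Reads and validates the plate CSV dialect used throughout the pipeline:
#' one row per well per plate per read, columns `plate_id`, `run_id`,
#' `read_time_min`, `well`, `row`, `col`, `sample_type`, `compound_id`,
#' `tau_ns`, `integrated_intensity`. Malformed well identifiers and
#' duplicated wells within a plate are rejected with the offending
#' file/row named.
#'
#' @param path CSV file path.
#' @return Validated plate data.frame.
#' @export
read_plate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "run_id", "read_time_min", "well", "row", "col",
            "sample_type", "compound_id", "tau_ns", "integrated_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  bad <- which(!grepl("^[A-Z]{1,2}[0-9]{2}$", df$well))
  if (length(bad) > 0)
    stop(sprintf("%s: malformed well id '%s' at data row %d",
                 path, df$well[bad[1]], bad[1]))
  dup <- duplicated(df[, c("plate_id", "well")])
  if (any(dup))
    stop(sprintf("%s: duplicate well '%s' in plate '%s' at data row %d",
                 path, df$well[which(dup)[1]], df$plate_id[which(dup)[1]],
                 which(dup)[1]))
  if (!all(df$sample_type %in% c("donor_acceptor", "donor_only", "unlabeled")))
    stop(path, ": sample_type must be donor_acceptor, donor_only or unlabeled")
  df
}

#' Read a two-column decay-waveform CSV
#'
#' @param path CSV with header columns `time_ns`, `counts`.
#' @param well_id,read_time Optional metadata attached to the waveform.
#' @return A `decay_waveform` data.frame.
#' @export
read_waveform <- function(path, well_id = NA_character_,
                          read_time = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(c("time_ns", "counts") %in% names(df)))
    stop(path, ": waveform CSV needs columns time_ns, counts")
  wf <- structure(df[, c("time_ns", "counts")], well_id = well_id,
                  read_time = read_time,
                  class = c("decay_waveform", "data.frame"))
  validate_waveform(wf)
  wf
}

#' Read a fiber trace with its solution-event sidecar
#'
#' @param trace_path CSV with columns `time_s`, `fluorescence`.
#' @param events_path Sidecar CSV with columns `time_s`, `label`.
#' @param calibration Optional [calibration_params()] attached to the trace.
#' @return A `fiber_trace` data.frame with the `events` attribute set.
#' @export
read_fiber_trace <- function(trace_path, events_path, calibration = NULL) {
  tr <- utils::read.csv(trace_path)
  ev <- utils::read.csv(events_path)
  if (!all(c("time_s", "fluorescence") %in% names(tr)))
    stop(trace_path, ": trace CSV needs columns time_s, fluorescence")
  if (!all(c("time_s", "label") %in% names(ev)))
    stop(events_path, ": events CSV needs columns time_s, label")
  if (is.unsorted(tr$time_s, strictly = TRUE))
    stop(trace_path, ": time must be strictly increasing")
  if (any(ev$time_s < min(tr$time_s)) || any(ev$time_s > max(tr$time_s)))
    stop(events_path, ": events must lie within the trace time span")
  structure(tr, events = data.frame(time = ev$time_s, label = ev$label),
            calibration = calibration,
            class = c("fiber_trace", "data.frame"))
}

#' Gaussian QC of the pooled screen E/E0 distribution
#'
#' Pools the compound-well E/E0 values of all normalized runs and fits the
#' central Gaussian (see [fit_control_gaussian()]). Because every well's
#' E/E0 is a ratio against its plate's estimated DMSO mean, the pooled-mean
#' estimator carries an extra plate-level variance component of
#' `sigma^2 / (n_control * n_runs)`; `se_mu_total` propagates it on top of
#' the within-well `se_mu`.
#'
#' @param normalized_runs List of `normalized_plate` objects, one per run.
#' @param robust Passed to [fit_control_gaussian()].
#' @return The Gaussian fit list plus `se_mu_total` and `n_runs`.
#' @export
screen_gaussian_qc <- function(normalized_runs, robust = FALSE) {
  pooled <- unlist(lapply(normalized_runs, function(nr)
    nr$E_ratio[nr$compound_id != "DMSO"]))
  fit <- fit_control_gaussian(pooled, robust = robust)
  n_ctrl <- mean(vapply(normalized_runs, attr, numeric(1), "n_control"))
  n_runs <- length(normalized_runs)
  fit$se_mu_total <- sqrt(fit$se_mu^2 + fit$sigma^2 / (n_ctrl * n_runs))
  fit$n_runs <- n_runs
  fit
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full screen analysis pipeline
#'
#' Composes the primary-screen stages end to end: simulate (or take) the
#' plate tables, normalize each run against its DMSO controls, apply the
#' donor-only and unlabeled-intensity false-hit filters, call hits at the
#' SD threshold, aggregate reproducibility across runs, and compute QC
#' (Z-prime from simulated DMSO/suramin reference plates, Gaussian fit of
#' the pooled E/E0 distribution, per-run hit rates). Deterministic given
#' the config seed; optionally writes a hit report CSV, a QC JSON and a
#' run log recording every threshold used.
#'
#' @param config A [screen_sim_config()]; its seed drives all simulation.
#' @param screen Optional pre-built `screen_sim` or plate data.frame (as
#'   from [read_plate_table()]); when given, `config` supplies thresholds
#'   context only for the log.
#' @param k_sd_hit Hit threshold in control SDs (default 4).
#' @param k_sd_filter False-hit filter threshold in control SDs (default 3).
#' @param min_runs Runs required for a reproducible hit (default 2).
#' @param robust_gaussian Use the robust (trimmed) Gaussian QC fit
#'   (default TRUE, so spiked hits do not inflate sigma).
#' @param out_dir Optional output directory for `hit_report.csv`, `qc.json`
#'   and `run_log.txt`.
#' @return A `screen_result` list: `per_run` (hit tables), `artifacts`,
#'   `reproducible` (aggregate table), `qc` (z_prime, gaussian, hit_rates),
#'   `thresholds`, `seed`, `config_hash`.
#' @export
run_screen_pipeline <- function(config = screen_sim_config(
                                  effect_table = demo_effect_table()),
                                screen = NULL, k_sd_hit = 4,
                                k_sd_filter = 3, min_runs = 2,
                                robust_gaussian = TRUE, out_dir = NULL) {
  stopifnot(k_sd_hit > 0, k_sd_filter > 0, min_runs >= 1)
  if (is.null(screen)) screen <- simulate_screen(config)
  plates <- if (inherits(screen, "screen_sim")) screen$plates else screen

  run_ids <- sort(unique(plates$run_id))
  normalized <- list(); hits <- list(); artifacts <- list()
  for (r in run_ids) {
    run <- plates[plates$run_id == r, ]
    normalized[[as.character(r)]] <- normalize_plate(run)
    artifacts[[as.character(r)]] <- filter_false_hits(run, k_sd = k_sd_filter)
    hits[[as.character(r)]] <- call_hits(normalized[[as.character(r)]],
                                         artifacts[[as.character(r)]],
                                         k_sd = k_sd_hit)
  }
  repro <- aggregate_reproducibility(hits, min_runs = min_runs)

  library_size <- sum(plates$run_id == run_ids[1] &
                        plates$sample_type == "donor_acceptor" &
                        plates$compound_id != "DMSO")
  rates <- vapply(hits, hit_rate, numeric(1), library_size = library_size)

  zp <- do.call(z_prime, unname(simulate_zprime_plates(
    donor_tau = config$donor_tau,
    fret_E_baseline = config$fret_E_baseline,
    lifetime_cv = config$donor_cv, seed = config$seed + 101L
  )[c("dmso_taus", "suramin_taus")]))
  gauss <- screen_gaussian_qc(normalized, robust = robust_gaussian)

  result <- structure(list(
    per_run = hits, artifacts = artifacts, normalized = normalized,
    reproducible = repro,
    qc = list(z_prime = zp, gaussian = gauss,
              hit_rates = stats::setNames(rates, paste0("run", run_ids)),
              library_size = library_size),
    thresholds = list(k_sd_hit = k_sd_hit, k_sd_filter = k_sd_filter,
                      min_runs = min_runs),
    seed = config$seed, config_hash = config_hash(config)
  ), class = "screen_result")

  if (!is.null(out_dir)) write_screen_result(result, out_dir)
  result
}

#' Write screen pipeline reports
#'
#' Emits `hit_report.csv` (the reproducibility table restricted to hits),
#' `qc.json` (Z-prime, Gaussian mu/sigma, hit rates, seed, config hash,
#' thresholds) and `run_log.txt` under `out_dir`. Reruns with the same
#' seed produce byte-identical files.
#'
#' @param result A `screen_result` from [run_screen_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_screen_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hit_path <- file.path(out_dir, "hit_report.csv")
  rep_hits <- result$reproducible[result$reproducible$reproducible_hit, ]
  rep_hits$mean_E_ratio <- round(rep_hits$mean_E_ratio, 6)
  rep_hits$se_E_ratio <- round(rep_hits$se_E_ratio, 6)
  utils::write.csv(rep_hits, hit_path, row.names = FALSE)

  qc_path <- file.path(out_dir, "qc.json")
  qc <- list(
    z_prime = result$qc$z_prime$z_prime,
    gaussian_mu = result$qc$gaussian$mu,
    gaussian_sigma = result$qc$gaussian$sigma,
    hit_rate = as.list(result$qc$hit_rates),
    library_size = result$qc$library_size,
    thresholds = result$thresholds,
    seed = result$seed, config_hash = result$config_hash
  )
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA)

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("seed: %d", result$seed),
    sprintf("config_hash: %s", result$config_hash),
    sprintf("hit threshold: > %g control SD (strict)",
            result$thresholds$k_sd_hit),
    sprintf("false-hit filters: > %g control SD on donor-only tau and unlabeled intensity",
            result$thresholds$k_sd_filter),
    sprintf("reproducible hit: same-sign hit in >= %d runs",
            result$thresholds$min_runs),
    sprintf("library size: %d compounds", result$qc$library_size),
    sprintf("hit rates: %s",
            paste(sprintf("%s=%.4f", names(result$qc$hit_rates),
                          result$qc$hit_rates), collapse = ", ")),
    sprintf("Z' = %.4f", result$qc$z_prime$z_prime),
    sprintf("pooled E/E0 Gaussian: mu = %.5f, sigma = %.5f (n = %d)",
            result$qc$gaussian$mu, result$qc$gaussian$sigma,
            result$qc$gaussian$n)
  ), log_path)
  invisible(c(hit_path, qc_path, log_path))
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("FLT-FRET screen result: %d runs, %d compounds\n",
              length(x$per_run), x$qc$library_size))
  cat(sprintf("  hit rates: %s\n",
              paste(sprintf("%.2f%%", 100 * x$qc$hit_rates), collapse = ", ")))
  cat(sprintf("  reproducible hits (>= %d runs, same sign): %d\n",
              x$thresholds$min_runs, sum(x$reproducible$reproducible_hit)))
  cat(sprintf("  Z' = %.3f; pooled E/E0 Gaussian mu = %.4f, sigma = %.4f\n",
              x$qc$z_prime$z_prime, x$qc$gaussian$mu, x$qc$gaussian$sigma))
  invisible(x)
}
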