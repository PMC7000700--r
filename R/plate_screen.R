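#' Default 1536-well screening layout
#'
#' The screening plate is a 32 x 48 grid. Library compounds occupy 40
#' columns (3-22 and 27-46, one compound per well: 1280 compound wells) and
#' the remaining 8 columns (1-2, 23-26, 47-48) hold DMSO-only no-drug
#' controls (256 control wells). Rows are labelled A..Z then AA..AF and
#' wells as e.g. "A01" or "AF48".
#'
#' @param compound_cols Integer columns holding library compounds.
#' @param control_cols Integer columns holding DMSO controls.
#' @return A `plate_layout` data.frame with columns `well`, `row`, `col`,
#'   `role` (`"compound"` or `"control"`), ordered column-major within role.
#' @examples
#' layout <- plate_layout_1536()
#' table(layout$role)
#' @export
plate_layout_1536 <- function(compound_cols = c(3:22, 27:46),
                              control_cols = c(1:2, 23:26, 47:48)) {
  if (length(intersect(compound_cols, control_cols)) > 0)
    stop("compound and control columns must be disjoint")
  if (any(c(compound_cols, control_cols) < 1) ||
      any(c(compound_cols, control_cols) > 48))
    stop("columns must lie in 1..48")
  rows <- c(LETTERS, paste0("A", LETTERS[1:6]))  # A..Z, AA..AF
  grid <- expand.grid(row = seq_len(32), col = sort(c(compound_cols, control_cols)),
                      KEEP.OUT.ATTRS = FALSE)
  grid$role <- ifelse(grid$col %in% compound_cols, "compound", "control")
  grid$well <- sprintf("%s%02d", rows[grid$row], grid$col)
  structure(grid[, c("well", "row", "col", "role")],
            class = c("plate_layout", "data.frame"))
}

control_stats <- function(x, what) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s)) stop("cannot compute control SD for ", what)
  list(mean = m, sd = s, n = length(x))
}

#' Normalize one screen run to its DMSO controls
#'
#' Computes per-well FRET efficiency and its DMSO-normalized form for the
#' donor-acceptor plate of one screen run. The plate-level donor lifetime
#' tau_D is the mean fitted lifetime of the donor-only plate's DMSO wells;
#' E = 1 - tau_DA / tau_D per well; E0 is the mean E of the donor-acceptor
#' plate's DMSO wells (optionally after excluding artifact-flagged wells),
#' and E/E0 is attached to every well.
#'
#' @param run A long-format plate table for one run: columns `well`, `row`,
#'   `col`, `sample_type` (`donor_acceptor`, `donor_only`, `unlabeled`),
#'   `compound_id` (`"DMSO"` for controls), `tau_ns`, `integrated_intensity`.
#' @param exclude Optional character vector of `well` ids to exclude from the
#'   E0/SD control estimate (artifact exclusion).
#' @return A `normalized_plate` data.frame: the donor-acceptor rows of `run`
#'   plus columns `E` and `E_ratio` (E/E0), with attributes `tau_D`, `E0`,
#'   `control_mean_ratio`, `control_sd_ratio`, `n_control`.
#' @export
normalize_plate <- function(run, exclude = NULL) {
  need <- c("well", "sample_type", "compound_id", "tau_ns")
  if (!all(need %in% names(run)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  da <- run[run$sample_type == "donor_acceptor", , drop = FALSE]
  don <- run[run$sample_type == "donor_only", , drop = FALSE]
  if (nrow(da) == 0 || nrow(don) == 0)
    stop("run must contain donor_acceptor and donor_only plates")

  tau_D <- mean(don$tau_ns[don$compound_id == "DMSO"])
  if (!is.finite(tau_D) || tau_D <= 0)
    stop("invalid donor-only DMSO lifetime mean")

  da$E <- fret_efficiency(da$tau_ns, tau_D)
  ctrl <- da$compound_id == "DMSO" & !(da$well %in% exclude)
  n_ctrl <- sum(ctrl)
  if (n_ctrl < 8)
    stop("fewer than 8 usable DMSO control wells; cannot estimate E0")
  E0 <- mean(da$E[ctrl])
  if (E0 == 0) stop("control mean FRET efficiency E0 is zero; cannot normalize")
  da$E_ratio <- da$E / E0

  cs <- control_stats(da$E_ratio[ctrl], "E/E0")
  structure(da, tau_D = tau_D, E0 = E0,
            control_mean_ratio = cs$mean, control_sd_ratio = cs$sd,
            n_control = n_ctrl,
            class = c("normalized_plate", "data.frame"))
}

#' Flag false hits from donor-only and unlabeled companion plates
#'
#' A compound whose fluorescence change does not come from FRET shows up in
#' the companion plates: a shift of the donor-only lifetime flags a direct
#' effect on the donor fluorophore, and a shift of the unlabeled-sample
#' integrated spectral intensity flags compound autofluorescence or optical
#' interference. A compound is flagged when its companion-plate value
#' deviates from that plate's DMSO-control mean by more than `k_sd` control
#' standard deviations. Flagged compounds are excluded from hit lists.
#'
#' @param run Long-format plate table for one run (see [normalize_plate()]).
#' @param k_sd SD multiple for the filters (default 3).
#' @return Data.frame with one row per compound: `compound_id`,
#'   `donor_only_artifact`, `intensity_artifact`, `flagged`.
#' @export
filter_false_hits <- function(run, k_sd = 3) {
  don <- run[run$sample_type == "donor_only", , drop = FALSE]
  unl <- run[run$sample_type == "unlabeled", , drop = FALSE]
  if (nrow(don) == 0 || nrow(unl) == 0)
    stop("run must contain donor_only and unlabeled companion plates")
  if (k_sd <= 0) stop("`k_sd` must be positive")

  dstat <- control_stats(don$tau_ns[don$compound_id == "DMSO"], "donor-only tau")
  istat <- control_stats(unl$integrated_intensity[unl$compound_id == "DMSO"],
                         "unlabeled intensity")

  dc <- don[don$compound_id != "DMSO", c("compound_id", "tau_ns")]
  uc <- unl[unl$compound_id != "DMSO", c("compound_id", "integrated_intensity")]
  flags <- merge(dc, uc, by = "compound_id", sort = TRUE)
  flags$donor_only_artifact <-
    abs(flags$tau_ns - dstat$mean) > k_sd * dstat$sd
  flags$intensity_artifact <-
    abs(flags$integrated_intensity - istat$mean) > k_sd * istat$sd
  flags$flagged <- flags$donor_only_artifact | flags$intensity_artifact
  flags[, c("compound_id", "donor_only_artifact", "intensity_artifact", "flagged")]
}

#' Call hits on a normalized plate
#'
#' A compound is a hit when its normalized FRET change exceeds the
#' hit threshold: |E/E0 - control mean E/E0| strictly greater than
#' `k_sd` times the control SD of E/E0 on that plate (the per-plate DMSO
#' wells define both), and the compound is not artifact-flagged. The signed
#' direction (FRET increase or decrease) is retained.
#'
#' @param normalized A `normalized_plate` from [normalize_plate()].
#' @param artifacts Optional output of [filter_false_hits()] for the same run.
#' @param k_sd SD multiple for the hit threshold (default 4).
#' @return Data.frame with one row per compound: `compound_id`, `E`,
#'   `E_ratio`, `delta_in_sd` (signed deviation in control-SD units), `hit`,
#'   `direction` (-1, 0, 1), `flagged`.
#' @export
call_hits <- function(normalized, artifacts = NULL, k_sd = 4) {
  if (!inherits(normalized, "normalized_plate"))
    stop("`normalized` must come from normalize_plate()")
  if (k_sd <= 0) stop("`k_sd` must be positive")
  mu <- attr(normalized, "control_mean_ratio")
  sdv <- attr(normalized, "control_sd_ratio")
  if (sdv == 0) stop("control SD of E/E0 is zero; hit threshold undefined")

  comp <- normalized[normalized$compound_id != "DMSO", , drop = FALSE]
  out <- data.frame(compound_id = comp$compound_id, E = comp$E,
                    E_ratio = comp$E_ratio,
                    delta_in_sd = (comp$E_ratio - mu) / sdv)
  out$flagged <- FALSE
  if (!is.null(artifacts)) {
    out$flagged <- out$compound_id %in%
      artifacts$compound_id[artifacts$flagged]
  }
  out$hit <- abs(out$delta_in_sd) > k_sd & !out$flagged  # strict ">"
  out$direction <- ifelse(out$hit, sign(out$delta_in_sd), 0)
  out[order(out$compound_id), ]
}

#' Aggregate hit reproducibility across screen runs
#'
#' A compound is a reproducible hit when it is called a hit, with the same
#' sign of FRET change, in at least `min_runs` of the runs. Opposite-sign
#' calls across runs are treated as irreproducible artifacts.
#'
#' @param hits_by_run List of per-run hit tables from [call_hits()]; all runs
#'   must cover the same compound library.
#' @param min_runs Minimum number of same-sign hit runs (default 2).
#' @return Data.frame per compound: `compound_id`, `n_runs_hit` (max
#'   same-sign hit count), `direction`, `reproducible_hit`, `mean_E_ratio`,
#'   `se_E_ratio` across runs.
#' @export
aggregate_reproducibility <- function(hits_by_run, min_runs = 2) {
  if (length(hits_by_run) < 2) stop("need at least 2 runs to aggregate")
  ids <- lapply(hits_by_run, function(h) sort(h$compound_id))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("runs have mismatched compound libraries")

  tabs <- lapply(hits_by_run, function(h) h[order(h$compound_id), ])
  ratio <- sapply(tabs, `[[`, "E_ratio")
  dirs <- sapply(tabs, `[[`, "direction")
  n_up <- rowSums(dirs > 0)
  n_dn <- rowSums(dirs < 0)
  n_hit <- pmax(n_up, n_dn)
  out <- data.frame(
    compound_id = tabs[[1]]$compound_id,
    n_runs_hit = n_hit,
    direction = ifelse(n_hit == 0, 0, ifelse(n_up >= n_dn, 1, -1)),
    reproducible_hit = n_hit >= min_runs,
    mean_E_ratio = rowMeans(ratio),
    se_E_ratio = apply(ratio, 1, stats::sd) / sqrt(ncol(ratio))
  )
  out
}

#' Z-prime screening-window statistic
#'
#' \eqn{Z' = 1 - 3(\sigma_{DMSO} + \sigma_{ref}) / |\mu_{ref} - \mu_{DMSO}|},
#' computed from the donor-acceptor lifetimes of DMSO-control wells and
#' reference wells (here 20 uM suramin, which abolishes the FRET signal).
#' Z' >= 0.5 marks an assay ready for large-scale screening.
#'
#' @param control_taus Numeric vector of control (DMSO) well lifetimes (n >= 2).
#' @param reference_taus Numeric vector of reference well lifetimes (n >= 2).
#' @return Z-prime list: `z_prime`, `mu_control`, `sd_control`, `mu_reference`,
#'   `sd_reference`.
#' @examples
#' z_prime(rnorm(100, 3.2, 0.016), rnorm(100, 4.0, 0.02))$z_prime
#' @export
z_prime <- function(control_taus, reference_taus) {
  if (length(control_taus) < 2 || length(reference_taus) < 2)
    stop("both groups need at least 2 wells")
  mu0 <- mean(control_taus); mu1 <- mean(reference_taus)
  if (mu0 == mu1) stop("Z' undefined: group means are equal")
  list(z_prime = 1 - 3 * (stats::sd(control_taus) + stats::sd(reference_taus)) /
         abs(mu1 - mu0),
       mu_control = mu0, sd_control = stats::sd(control_taus),
       mu_reference = mu1, sd_reference = stats::sd(reference_taus))
}

#' Fit a Gaussian to the screen's normalized FRET distribution
#'
#' Maximum-likelihood Gaussian fit (sample mean; SD with the 1/n MLE
#' denominator) to pooled E/E0 values, summarizing the central
#' control-like distribution of a screen. With `robust = TRUE`, values
#' further than 4 robust z-units (median/MAD) from the center are trimmed
#' before the fit, so a small fraction of genuine large-effect compounds
#' does not inflate sigma.
#'
#' @param x Numeric vector of pooled E/E0 values (n >= 50).
#' @param robust Trim |z| > 4 outliers (median/MAD z) before fitting.
#' @return List `mu`, `sigma`, `se_mu`, `se_sigma`, `n` (values used).
#' @export
fit_control_gaussian <- function(x, robust = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 50) stop("need at least 50 values to fit the Gaussian")
  if (robust) {
    s <- stats::mad(x)
    if (s > 0) x <- x[abs(x - stats::median(x)) / s <= 4]
  }
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))  # MLE
  if (sigma == 0) warning("degenerate Gaussian fit: all values equal")
  list(mu = mu, sigma = sigma,
       se_mu = sigma / sqrt(n), se_sigma = sigma / sqrt(2 * n), n = n)
}

#' Per-run hit rate
#'
#' @param hits A hit table from [call_hits()] or a logical vector of hit flags.
#' @param library_size Number of library compounds screened (> 0).
#' @return Fraction of the library called as hits (in `[0, 1]`).
#' @export
hit_rate <- function(hits, library_size) {
  if (library_size <= 0) stop("`library_size` must be positive")
  n_hit <- if (is.data.frame(hits)) sum(hits$hit) else sum(hits)
  n_hit / library_size
}
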