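#' Hill dose-response function
#'
#' \eqn{R(c) = bottom + (top - bottom) / (1 + (c/IC50)^h)}: the response
#' runs from `top` at low concentration to `bottom` at high concentration
#' (for h > 0), crossing the midpoint at c = IC50 for any slope.
#'
#' @param conc Concentrations (same units as `ic50`).
#' @param bottom,top Lower and upper asymptotes.
#' @param ic50 Half-maximal concentration (> 0).
#' @param hill_coefficient Hill slope h.
#' @return Responses at `conc`.
#' @export
hill_response <- function(conc, bottom, top, ic50, hill_coefficient = 1) {
  if (ic50 <= 0) stop("`ic50` must be positive")
  bottom + (top - bottom) / (1 + (conc / ic50)^hill_coefficient)
}

#' Normalize radioligand binding against its controls
#'
#' Maps raw [3H]ryanodine binding counts onto the 0-1 scale defined by the
#' assay controls: the no-drug DMSO control maps to 1 and the nonspecific
#' binding level (excess unlabeled ryanodine) maps to 0. Affine and
#' order-preserving.
#'
#' @param raw Raw binding counts (vectorized).
#' @param dmso_control Mean counts of the DMSO (no-drug) control.
#' @param nonspecific Mean counts of the nonspecific-binding control.
#' @return Normalized response `(raw - nonspecific) / (dmso - nonspecific)`.
#' @examples
#' normalize_binding(c(500, 300, 100), dmso_control = 500, nonspecific = 100)
#' @export
normalize_binding <- function(raw, dmso_control, nonspecific) {
  if (dmso_control <= nonspecific)
    stop("DMSO control must exceed the nonspecific level")
  (raw - nonspecific) / (dmso_control - nonspecific)
}

#' Fit the Hill function to a dose-response series
#'
#' Least-squares fit of the four-parameter Hill model on log10
#' concentration, with a deterministic initialization: `top`/`bottom` from
#' the extreme-concentration means, IC50 from the concentration where the
#' mean response crosses the midpoint (log-linear interpolation), slope 1.
#' Standard errors come from the fit covariance; the IC50 SE uses the delta
#' method on log10(IC50). `fix_hill = 1` gives the three-parameter variant.
#'
#' @param series A `dose_response_series` (or any data.frame with `conc_uM`
#'   and `response`), or a numeric concentration vector when `response` is
#'   given.
#' @param response Optional response vector matching `series` as
#'   concentrations.
#' @param fix_hill Fix the Hill slope at this value (`NULL` = free).
#' @return A `hill_fit` list: `bottom`, `top`, `ic50`, `hill_coefficient`,
#'   `se` (named vector incl. `ic50`), `residual_rss`, `converged`,
#'   `poorly_constrained` (SE(IC50)/IC50 > 1), `n`.
#' @export
fit_hill <- function(series, response = NULL, fix_hill = NULL) {
  if (is.data.frame(series)) {
    conc <- series$conc_uM
    resp <- series$response
  } else {
    conc <- series
    resp <- response
  }
  if (is.null(resp) || length(resp) != length(conc))
    stop("need matching concentration and response vectors")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations to fit the Hill model")

  lc <- log10(conc)
  means <- tapply(resp, lc, mean)
  mlc <- as.numeric(names(means))
  lo <- means[[which.min(mlc)]]  # response at lowest concentration
  hi <- means[[which.max(mlc)]]
  top0 <- lo; bottom0 <- hi     # canonical: top at low c (h > 0)
  mid <- (top0 + bottom0) / 2
  cross <- which(diff(sign(means - mid)) != 0)
  l50_0 <- if (length(cross) > 0) {
    i <- cross[1]
    mlc[i] + (mid - means[[i]]) / (means[[i + 1]] - means[[i]]) *
      (mlc[i + 1] - mlc[i])
  } else stats::median(mlc)

  dat <- data.frame(lc = lc, y = resp)
  fit <- tryCatch({
    if (is.null(fix_hill)) {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(h * (lc - l50))), data = dat,
        start = list(bottom = bottom0, top = top0, l50 = l50_0, h = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      h_fixed <- fix_hill
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(h_fixed * (lc - l50))),
        data = dat,
        start = list(bottom = bottom0, top = top0, l50 = l50_0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(
      bottom = bottom0, top = top0, ic50 = 10^l50_0,
      hill_coefficient = if (is.null(fix_hill)) 1 else fix_hill,
      se = c(ic50 = NA_real_), residual_rss = NA_real_, converged = FALSE,
      poorly_constrained = TRUE, n = length(resp),
      message = conditionMessage(fit)
    ), class = "hill_fit"))
  }

  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  ses <- if (is.null(vc)) rep(NA_real_, length(cf)) else sqrt(diag(vc))
  names(ses) <- names(cf)
  ic50 <- 10^cf[["l50"]]
  se_ic50 <- if (is.finite(ses[["l50"]])) log(10) * ic50 * ses[["l50"]]
             else NA_real_

  bottom <- cf[["bottom"]]; top <- cf[["top"]]
  h <- if (is.null(fix_hill)) cf[["h"]] else fix_hill
  if (bottom > top) {  # canonical ordering: flip the branch
    tmp <- bottom; bottom <- top; top <- tmp; h <- -h
  }
  pc <- is.finite(se_ic50) && se_ic50 / ic50 > 1
  if (pc) warning("IC50 poorly constrained: SE(IC50)/IC50 > 1")
  structure(list(
    bottom = bottom, top = top, ic50 = ic50, hill_coefficient = h,
    se = c(bottom = ses[["bottom"]], top = ses[["top"]], ic50 = se_ic50,
           hill = if (is.null(fix_hill)) ses[["h"]] else 0),
    residual_rss = sum(stats::residuals(fit)^2), converged = TRUE,
    poorly_constrained = pc, n = length(resp), message = "converged"
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: IC50 = %.3g +/- %.2g, slope = %.2f, range [%.3g, %.3g]\n",
    x$ic50, x$se[["ic50"]], x$hill_coefficient, x$bottom, x$top))
  invisible(x)
}

#' Detect a biphasic (non-monotone) dose-response
#'
#' Some modulators raise the FRET readout at sub-micromolar doses and lower
#' it at micromolar doses; a monotone Hill fit is then the wrong model and
#' the series should be reported as biphasic rather than force-fit. The
#' detector measures peak-contrast evidence on the per-concentration means:
#' for every interior concentration, the smaller of the two excursions from
#' the lowest mean on its left and on its right (and the mirrored trough
#' version); the maximum over interior positions is the test statistic. Its
#' null distribution is obtained by parametric bootstrap around the best
#' monotone description of the data (isotonic regression of the means,
#' fitted in both directions, with the pooled within-concentration noise),
#' so a monotone series of any shape is not flagged.
#'
#' @param series Data.frame with `conc_uM` and `response` (>= 6 distinct
#'   concentrations, replicated).
#' @param alpha Test level (default 0.05).
#' @param n_boot Bootstrap draws (default 399).
#' @param seed Seed for the bootstrap (local RNG).
#' @return List: `biphasic` flag, `p_value`, `stat` (peak contrast in
#'   response units), `turn_conc_uM` (turning-point concentration, or NA).
#' @export
detect_biphasic <- function(series, alpha = 0.05, n_boot = 399, seed = 1L) {
  conc <- series$conc_uM
  resp <- series$response
  concs <- sort(unique(conc))
  m <- length(concs)
  if (m < 6)
    stop("need at least 6 distinct concentrations to assess biphasicity")

  means <- vapply(concs, function(cc) mean(resp[conc == cc]), numeric(1))
  ns <- vapply(concs, function(cc) sum(conc == cc), numeric(1))
  rss_s <- sum((resp - means[match(conc, concs)])^2)
  df_s <- length(resp) - m
  sigma <- if (df_s > 0) sqrt(rss_s / df_s) else 0

  peak_stat <- function(mu) {
    best <- -Inf; turn <- NA_integer_
    for (i in 2:(m - 1)) {
      left <- mu[seq_len(i - 1)]; right <- mu[seq(i + 1, m)]
      s <- max(min(mu[i] - min(left), mu[i] - min(right)),   # peak at i
               min(max(left) - mu[i], max(right) - mu[i]))   # trough at i
      if (s > best) { best <- s; turn <- i }
    }
    list(stat = best, turn = turn)
  }
  obs <- peak_stat(means)

  # best monotone null: isotonic regression of the means, either direction
  iso_up <- stats::isoreg(seq_len(m), means)$yf
  iso_dn <- -stats::isoreg(seq_len(m), -means)$yf
  mu0 <- if (sum(ns * (means - iso_up)^2) <= sum(ns * (means - iso_dn)^2))
    iso_up else iso_dn

  stat_b <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    peak_stat(mu0 + stats::rnorm(m, 0, sigma / sqrt(ns)))$stat
  }, numeric(1)))
  p <- (1 + sum(stat_b >= obs$stat)) / (n_boot + 1)
  list(biphasic = p < alpha, p_value = p, stat = obs$stat,
       turn_conc_uM = concs[obs$turn])
}
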