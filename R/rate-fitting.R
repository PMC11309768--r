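#' Fit a mono-exponential decay to an intensity series
#'
#' Fits I(t) = I0 * exp(-R * t) by least squares. The initial guess is
#' deterministic: I0 = max height, R = log(I_first / I_last) / (t_last -
#' t_first) clipped to \[1e-3, 1e3\] s^-1, so repeated fits of the same data
#' are identical. Duplicate delay points enter as separate observations.
#'
#' @param series an [intensity_series()] with >= 3 distinct observed delays.
#' @return list of class `rate_estimate`: `residue`, `rate` (s^-1), `I0`,
#'   `rate_sigma` (NA until Monte-Carlo errors are attached), `fit_rss`.
#'   A non-positive fitted I0 triggers a warning but the result is returned.
#' @export
fit_monoexponential <- function(series) {
  pts <- series_points(series)
  if (length(unique(pts$time)) < 3)
    stop(sprintf("residue %d: need >= 3 distinct delays, got %d",
                 series$residue$number, length(unique(pts$time))))
  fit <- .fit_monoexp_xy(pts$time, pts$height)
  if (fit$I0 <= 0)
    warning(sprintf("residue %d: non-positive fitted amplitude (I0 = %g)",
                    series$residue$number, fit$I0))
  structure(list(residue = series$residue, rate = fit$rate, I0 = fit$I0,
                 rate_sigma = NA_real_, fit_rss = fit$rss),
            class = "rate_estimate")
}

# core least-squares on (t, I) vectors; deterministic initial guess
.fit_monoexp_xy <- function(t, I) {
  o <- order(t)
  t1 <- t[o][1]; t2 <- t[o][length(t)]
  I1 <- I[o][1]; I2 <- I[o][length(t)]
  R0 <- if (I1 > 0 && I2 > 0 && t2 > t1) log(I1 / I2) / (t2 - t1) else 1
  if (!is.finite(R0)) R0 <- 1
  R0 <- min(max(abs(R0), 1e-3), 1e3) * sign(if (R0 == 0) 1 else R0)
  if (R0 <= 0) R0 <- 1e-3
  I0g <- max(I)
  df <- data.frame(t = t, I = I)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 * exp(-R * t), data = df,
                      start = list(I0 = I0g, R = R0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to log-linear regression on positive heights
    pos <- I > 0
    if (sum(pos) < 3) stop("exponential fit failed and too few positive heights")
    cf <- stats::coef(stats::lm(log(I[pos]) ~ t[pos]))
    co <- c(I0 = exp(cf[[1]]), R = -cf[[2]])
  } else co <- stats::coef(fit)
  pred <- co[["I0"]] * exp(-co[["R"]] * t)
  list(I0 = co[["I0"]], rate = co[["R"]], rss = sum((I - pred)^2))
}

#' Estimate intensity noise from duplicate delay points
#'
#' For each residue, sigma = sqrt( sum(d_i^2) / (2 m) ) over the m duplicate
#' pairs, where d_i is the height difference within pair i. With
#' `pool = TRUE` the pairs of all residues are pooled into a single sigma.
#'
#' @param series_list list of [intensity_series()] over a schedule with at
#'   least one duplicate-flagged delay.
#' @param pool pool pairs across residues (single value) instead of the
#'   default per-residue estimates.
#' @return named numeric vector of sigmas (per residue), or scalar if pooled.
#' @export
estimate_noise_from_duplicates <- function(series_list, pool = FALSE) {
  if (inherits(series_list, "intensity_series")) series_list <- list(series_list)
  diffs_per <- lapply(series_list, function(s) {
    ex <- expand_schedule(s$schedule)
    if (all(is.na(ex$pair)))
      stop("schedule has no duplicate delays; supply noise_sigma explicitly")
    pr <- unique(ex$pair[!is.na(ex$pair)])
    d <- vapply(pr, function(p) {
      h <- s$heights[which(ex$pair == p)]
      if (anyNA(h)) NA_real_ else diff(h)
    }, numeric(1))
    d[!is.na(d)]
  })
  if (pool) {
    d <- unlist(diffs_per)
    if (!length(d)) stop("no complete duplicate pairs available")
    return(sqrt(sum(d^2) / (2 * length(d))))
  }
  out <- vapply(diffs_per, function(d)
    if (length(d)) sqrt(sum(d^2) / (2 * length(d))) else NA_real_, numeric(1))
  names(out) <- vapply(series_list, function(s) as.character(s$residue$number), "")
  out
}

#' Monte-Carlo uncertainty of a fitted rate
#'
#' Generates `n` synthetic replicates of the best-fit curve with Gaussian
#' noise of standard deviation `sigma`, refits each, and returns the standard
#' deviation of the refitted rates. `sigma = 0` returns 0 without simulation.
#'
#' @param series an [intensity_series()].
#' @param sigma intensity noise (absolute units of the heights).
#' @param n number of replicates (default 500).
#' @param seed RNG seed for reproducibility.
#' @param fit the fit to perturb; defaults to `fit_monoexponential(series)`.
#' @return rate standard deviation (s^-1).
#' @export
monte_carlo_uncertainty <- function(series, sigma, n = 500, seed = NULL,
                                    fit = NULL) {
  stopifnot(sigma >= 0, n >= 2)
  if (sigma == 0) return(0)
  if (is.null(fit)) fit <- suppressWarnings(fit_monoexponential(series))
  pts <- series_points(series)
  ideal <- fit$I0 * exp(-fit$rate * pts$time)
  rates <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      y <- ideal + stats::rnorm(length(ideal), 0, sigma)
      tryCatch(.fit_monoexp_xy(pts$time, y)$rate, error = function(e) NA_real_)
    }, numeric(1))
  })
  stats::sd(rates, na.rm = TRUE)
}

#' Steady-state heteronuclear nOe from saturated/unsaturated peak heights
#'
#' nOe = I_sat / I_unsat; the uncertainty propagates the baseline-noise RMSD
#' of the two spectra: sigma = |nOe| * sqrt((rmsd_sat/I_sat)^2 +
#' (rmsd_unsat/I_unsat)^2). Negative nOe values (flexible termini) pass
#' through unchanged.
#'
#' @param residue a [residue_id()].
#' @param sat_height,unsat_height peak heights with and without 1H
#'   saturation; `unsat_height` must be non-zero.
#' @param rmsd_sat,rmsd_unsat baseline-noise RMSDs of the two spectra.
#' @return list of class `noe_estimate`: `residue`, `noe`, `noe_sigma`.
#' @export
compute_noe <- function(residue, sat_height, unsat_height,
                        rmsd_sat = 0, rmsd_unsat = 0) {
  if (unsat_height == 0) stop("unsaturated peak height is zero")
  noe <- sat_height / unsat_height
  sig <- if (sat_height == 0) abs(rmsd_sat / unsat_height)
         else abs(noe) * sqrt((rmsd_sat / sat_height)^2 +
                              (rmsd_unsat / unsat_height)^2)
  structure(list(residue = residue, noe = noe, noe_sigma = sig),
            class = "noe_estimate")
}

#' Effective transverse relaxation rate from a constant-time CPMG experiment
#'
#' R2,eff = -(1/Trelax) * log(I_nu / I_ref). Vectorized over `I_nu`.
#'
#' @param I_nu peak height(s) at a given CPMG frequency (> 0).
#' @param I_ref reference height (> 0, zero-length CPMG block).
#' @param Trelax constant relaxation time, s (e.g. 0.040).
#' @return rate(s), s^-1.
#' @export
compute_r2eff <- function(I_nu, I_ref, Trelax) {
  if (any(I_nu <= 0) || I_ref <= 0) stop("intensities must be positive")
  if (Trelax <= 0) stop("Trelax must be positive")
  -log(I_nu / I_ref) / Trelax
}

#' Per-residue CPMG dispersion series
#' @param residue a [residue_id()].
#' @param nu_cpmg CPMG frequencies, Hz (> 0).
#' @param r2eff effective rates, s^-1, one per frequency.
#' @param Trelax constant relaxation time, s.
#' @param sigma optional per-point rate uncertainties.
#' @return object of class `cpmg_series`.
#' @export
cpmg_series <- function(residue, nu_cpmg, r2eff, Trelax, sigma = NULL) {
  stopifnot(all(nu_cpmg > 0), Trelax > 0, length(nu_cpmg) == length(r2eff))
  structure(list(residue = residue, nu_cpmg = as.numeric(nu_cpmg),
                 r2eff = as.numeric(r2eff), Trelax = Trelax, sigma = sigma),
            class = "cpmg_series")
}

#' Assess whether a CPMG profile is dispersive
#'
#' Compares the observed drop from the lowest to the highest CPMG frequency
#' with the noise level, and runs an F-test of a two-parameter monotone
#' dispersion surrogate R(nu) = a + b * nu_min/nu against the constant
#' model. A profile is called dispersive only if the amplitude exceeds
#' `k * sigma` and the F-test is significant at `alpha`.
#'
#' @param series a [cpmg_series()] with >= 4 points.
#' @param sigma pooled rate noise (s^-1); defaults to the series' sigmas or,
#'   failing that, the residual SD of the constant model.
#' @param k amplitude threshold multiplier (default 2).
#' @param alpha F-test significance level (default 0.05).
#' @return list: `dispersive` (flag), `amplitude` (s^-1), `p_value`.
#' @export
assess_dispersion <- function(series, sigma = NULL, k = 2, alpha = 0.05) {
  nu <- series$nu_cpmg; y <- series$r2eff
  if (length(nu) < 4) stop("need >= 4 CPMG points to assess dispersion")
  amp <- mean(y[nu == min(nu)]) - mean(y[nu == max(nu)])
  if (is.null(sigma))
    sigma <- if (!is.null(series$sigma)) sqrt(mean(series$sigma^2))
             else stats::sd(y)
  # constant model vs 2-parameter surrogate a + b * (nu_min / nu)
  x <- min(nu) / nu
  fit <- stats::lm(y ~ x)
  rss1 <- sum((y - mean(y))^2)
  rss2 <- sum(stats::residuals(fit)^2)
  n <- length(y)
  Fstat <- (rss1 - rss2) / (rss2 / (n - 2))
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(dispersive = (amp > k * sigma) && (p < alpha) &&
         stats::coef(fit)[["x"]] > 0,
       amplitude = amp, p_value = p)
}

#' Mean and SEM of an observable over a residue window
#'
#' Unweighted mean and standard error of the mean (sd/sqrt(n)) over the
#' residues present in the window for the requested observable -- e.g. the
#' core-region averages quoted for 68 dsRBD2 core residues (159-227).
#'
#' @param table a [rate_table()].
#' @param window inclusive residue range, length 2.
#' @param kind observable kind (R1, R2, nOe, ...).
#' @param field spectrometer field, MHz.
#' @param state "apo" or "bound".
#' @param cond optional condition filter (HSn / nuCPMG).
#' @return list: `mean`, `sem`, `n`.
#' @export
aggregate_region_stats <- function(table, window, kind, field, state,
                                   cond = NULL) {
  sel <- filter_rates(table, kind = kind, field = field, state = state,
                      cond = cond, window = window)
  if (nrow(sel) < 2)
    stop(sprintf("fewer than 2 matching residues in window [%d, %d]",
                 window[1], window[2]))
  v <- sel$value
  list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
}

#' Fit rates for a collection of intensity series
#'
#' Convenience wrapper: mono-exponential fit per residue, duplicate-based
#' noise estimation (per-residue with pooled fallback), and Monte-Carlo rate
#' uncertainties.
#'
#' @param series_list list of [intensity_series()].
#' @param kind observable kind to label the rows with (R1, R2, R1rho, R2rho).
#' @param field field, MHz; `state` "apo"/"bound"; `cond` optional condition.
#' @param state,cond row labels, see [rate_table()].
#' @param mc_n Monte-Carlo replicates (default 500); `seed` RNG seed.
#' @param seed RNG seed for the Monte-Carlo noise draws.
#' @return a [rate_table()].
#' @export
fit_rate_series <- function(series_list, kind = "R1", field = 600,
                            state = "apo", cond = NA_character_,
                            mc_n = 500, seed = NULL) {
  sig <- tryCatch(estimate_noise_from_duplicates(series_list),
                  error = function(e) NULL)
  pooled <- tryCatch(estimate_noise_from_duplicates(series_list, pool = TRUE),
                     error = function(e) NA_real_)
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    fit <- suppressWarnings(fit_monoexponential(s))
    s_i <- if (!is.null(s$noise_sigma)) s$noise_sigma
           else if (!is.null(sig) && is.finite(sig[[i]]) && sig[[i]] > 0) sig[[i]]
           else pooled
    rs <- if (is.finite(s_i) && s_i > 0)
      monte_carlo_uncertainty(s, s_i, n = mc_n,
                              seed = if (is.null(seed)) NULL else seed + i,
                              fit = fit)
    else 0
    data.frame(residue = s$residue$number, kind = kind, value = fit$rate,
               sigma = rs, field = field, state = state, cond = cond)
  })
  rate_table(do.call(rbind, rows))
}
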