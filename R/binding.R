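#' Single-site binding model
#'
#' Shared parameter container for the NMR titration isotherm and the ITC
#' single-site model.
#'
#' @param Kd dissociation constant, M (> 0).
#' @param dH binding enthalpy, kcal/mol.
#' @param n stoichiometry (sites per macromolecule, > 0).
#' @param ddmax maximum response change at saturation (peak-intensity units
#'   or ppm, depending on the titration readout).
#' @return object of class `binding_model`.
#' @export
binding_model <- function(Kd, dH = 0, n = 1, ddmax = 1) {
  stopifnot(Kd > 0, n > 0)
  structure(list(Kd = Kd, dH = dH, n = n, ddmax = ddmax),
            class = "binding_model")
}

#' Equilibrium two-state complex concentration
#'
#' Quadratic solution of P + L <-> PL:
#' \[PL\] = ((Pt + Lt + Kd) - sqrt((Pt + Lt + Kd)^2 - 4 Pt Lt)) / 2.
#'
#' @param Pt,Lt total protein and ligand concentrations, M (>= 0).
#' @param Kd dissociation constant, M (> 0).
#' @return list: `complex` (M), `fraction_P`, `fraction_L`.
#' @export
solve_fraction_bound <- function(Pt, Lt, Kd) {
  stopifnot(Pt >= 0, Lt >= 0, Kd > 0)
  s <- Pt + Lt + Kd
  disc <- pmax(s^2 - 4 * Pt * Lt, 0)
  pl <- (s - sqrt(disc)) / 2
  list(complex = pl,
       fraction_P = if (Pt > 0) pl / Pt else 0,
       fraction_L = if (Lt > 0) pl / Lt else 0)
}

#' NMR titration curve
#'
#' Per-residue titration response (peak-intensity change or chemical shift)
#' versus total ligand at fixed total protein. The response type is recorded
#' but the two are not asserted interchangeable.
#'
#' @param Pt total protein, M.
#' @param Lt total ligand per point, M, non-negative and strictly increasing.
#' @param ddobs observed response change per point.
#' @param sigma optional per-point noise.
#' @param response `"intensity"` or `"shift"`.
#' @return object of class `titration_curve`.
#' @export
titration_curve <- function(Pt, Lt, ddobs, sigma = NULL,
                            response = c("intensity", "shift")) {
  response <- match.arg(response)
  stopifnot(Pt > 0, all(Lt >= 0), all(diff(Lt) > 0),
            length(Lt) == length(ddobs))
  structure(list(Pt = Pt, Lt = as.numeric(Lt), ddobs = as.numeric(ddobs),
                 sigma = sigma, response = response),
            class = "titration_curve")
}

#' One-site titration isotherm
#'
#' ddobs = ddmax * ((Pt + Lt + Kd) - sqrt((Pt + Lt + Kd)^2 - 4 Pt Lt))
#'         / (2 Pt).
#'
#' @param Pt,Lt totals, M; `Kd` M; `ddmax` response units.
#' @param Kd dissociation constant, M.
#' @param ddmax saturating response change.
#' @return response values, vectorized over `Lt`.
#' @export
titration_isotherm <- function(Pt, Lt, Kd, ddmax) {
  s <- Pt + Lt + Kd
  ddmax * (s - sqrt(pmax(s^2 - 4 * Pt * Lt, 0))) / (2 * Pt)
}

#' Fit the one-site titration isotherm
#'
#' Least-squares fit of (Kd, ddmax) to a [titration_curve()], with seeded
#' Monte-Carlo parameter uncertainties. When the titration does not reach
#' the inflection region (max Lt < fitted Kd, or the curve stops well short
#' of saturation) an under-sampling warning is raised -- the situation the
#' line-broadened titrations of dsRBD2 ran into.
#'
#' @param curve a [titration_curve()] with >= 4 points.
#' @param mc_n Monte-Carlo replicates (default 500; 0 disables).
#' @param seed RNG seed.
#' @return list of class `titration_fit`: `Kd`, `ddmax`, `Kd_sigma`,
#'   `ddmax_sigma`, `undersampled`.
#' @export
fit_titration <- function(curve, mc_n = 500, seed = NULL) {
  if (length(curve$Lt) < 4) stop("need >= 4 titration points")
  df <- data.frame(L = curve$Lt, y = curve$ddobs)
  Pt <- curve$Pt
  kd0 <- max(stats::median(curve$Lt), 1e-9)
  dd0 <- max(abs(curve$ddobs))
  if (dd0 == 0) dd0 <- 1
  fit <- minpack.lm::nlsLM(
    y ~ titration_isotherm(Pt, L, Kd, ddmax), data = df,
    start = list(Kd = kd0, ddmax = dd0),
    lower = c(1e-12, -Inf), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  co <- stats::coef(fit)
  undersampled <- max(curve$Lt) < co[["Kd"]] ||
    max(abs(curve$ddobs)) < 0.8 * abs(co[["ddmax"]])
  if (undersampled)
    warning("titration under-sampled near the inflection point; Kd poorly constrained")
  kd_sd <- dd_sd <- NA_real_
  if (mc_n > 0) {
    pred <- titration_isotherm(Pt, curve$Lt, co[["Kd"]], co[["ddmax"]])
    sig <- if (!is.null(curve$sigma)) rep(curve$sigma, length.out = length(pred))
           else rep(stats::sd(curve$ddobs - pred), length(pred))
    sims <- with_seed(seed, {
      replicate(mc_n, {
        y2 <- pred + stats::rnorm(length(pred), 0, sig)
        f2 <- tryCatch(minpack.lm::nlsLM(
          y2 ~ titration_isotherm(Pt, L, Kd, ddmax),
          data = data.frame(L = curve$Lt, y2 = y2),
          start = as.list(co), lower = c(1e-12, -Inf), upper = c(1, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(f2)) c(NA, NA) else stats::coef(f2)
      })
    })
    kd_sd <- stats::sd(sims[1, ], na.rm = TRUE)
    dd_sd <- stats::sd(sims[2, ], na.rm = TRUE)
  }
  structure(list(Kd = co[["Kd"]], ddmax = co[["ddmax"]],
                 Kd_sigma = kd_sd, ddmax_sigma = dd_sd,
                 undersampled = undersampled),
            class = "titration_fit")
}

#' Combined 1H/15N chemical shift perturbation
#'
#' CSP = sqrt(ddH^2 + (alphaN * ddN)^2), with the conventional nitrogen
#' weight alphaN = 0.14.
#'
#' @param ddH,ddN amide 1H and 15N shift changes, ppm.
#' @param alphaN nitrogen scaling factor in (0, 1\].
#' @return combined CSP, ppm (vectorized).
#' @export
compute_csp <- function(ddH, ddN, alphaN = 0.14) {
  stopifnot(alphaN > 0, alphaN <= 1)
  sqrt(ddH^2 + (alphaN * ddN)^2)
}

#' ITC experiment geometry and observed heats
#'
#' @param V0 cell volume, L (default 200 uL, PEAQ-class instrument).
#' @param cell_conc cell (macromolecule) concentration, M.
#' @param syringe_conc syringe (titrant) concentration, M.
#' @param inj_vol injection volumes, L; the first is the customary small
#'   discardable injection.
#' @param heats observed heats per retained injection, ucal (optional until
#'   measured/simulated).
#' @param discard_first drop the first injection from analysis (default
#'   TRUE).
#' @param temperature K (default 298.15).
#' @return object of class `itc_experiment`.
#' @export
itc_experiment <- function(V0 = 200e-6, cell_conc, syringe_conc,
                           inj_vol = c(0.4e-6, rep(2e-6, 18)),
                           heats = NULL, discard_first = TRUE,
                           temperature = 298.15) {
  stopifnot(V0 > 0, all(inj_vol > 0), cell_conc > 0)
  if (syringe_conc <= 0) stop("syringe concentration must be > 0")
  n_ret <- length(inj_vol) - as.integer(discard_first)
  if (!is.null(heats) && length(heats) != n_ret)
    stop(sprintf("%d heats for %d retained injections", length(heats), n_ret))
  structure(list(V0 = V0, cell_conc = cell_conc, syringe_conc = syringe_conc,
                 inj_vol = inj_vol, heats = heats,
                 discard_first = discard_first, temperature = temperature),
            class = "itc_experiment")
}

# cumulative cell concentrations after each injection with the standard
# displaced-volume dilution (Origin/PEAQ convention): dilution factor
# (1 - dV/(2 V0)) / (1 + dV/(2 V0)) for the resident species and
# Xs * (dV/V0) / (1 + dV/(2 V0)) for the added titrant.
.itc_concentrations <- function(exp) {
  k <- length(exp$inj_vol)
  Mt <- Xt <- numeric(k)
  dVcum <- cumsum(exp$inj_vol)
  for (i in seq_len(k)) {
    d <- dVcum[i] / exp$V0
    Mt[i] <- exp$cell_conc * (1 - d / 2) / (1 + d / 2)
    Xt[i] <- exp$syringe_conc * d / (1 + d / 2)
  }
  list(Mt = Mt, Xt = Xt)
}

#' Simulate a single-site ITC thermogram
#'
#' Cumulative heat content Q(i) = n Theta(i) Mt(i) dH V0, with the bound
#' fraction Theta from the quadratic single-site binding polynomial, and the
#' per-injection heat corrected for the displaced volume:
#' dQ(i) = Q(i) + (dVi/V0) (Q(i) + Q(i-1))/2 - Q(i-1). The first (small)
#' injection is simulated but its heat discarded, as in analysis practice.
#'
#' @param model a [binding_model()] (Kd in M, dH in kcal/mol, n sites).
#' @param experiment an [itc_experiment()] (heats ignored).
#' @param sigma Gaussian heat noise, ucal (absolute; default 0).
#' @param seed RNG seed.
#' @return the experiment with `heats` filled in (ucal, retained
#'   injections).
#' @export
simulate_itc <- function(model, experiment, sigma = 0, seed = NULL) {
  conc <- .itc_concentrations(experiment)
  k <- length(experiment$inj_vol)
  # kcal -> ucal: 1 kcal = 1e9 ucal
  dH_ucal <- model$dH * 1e9
  Q <- numeric(k)
  for (i in seq_len(k)) {
    r <- solve_fraction_bound(model$n * conc$Mt[i], conc$Xt[i], model$Kd)
    theta <- if (conc$Mt[i] > 0) r$complex / (model$n * conc$Mt[i]) else 0
    Q[i] <- model$n * theta * conc$Mt[i] * dH_ucal * experiment$V0
  }
  Qprev <- c(0, Q[-k])
  dQ <- Q + (experiment$inj_vol / experiment$V0) * (Q + Qprev) / 2 - Qprev
  keep <- if (experiment$discard_first) -1 else seq_len(k)
  heats <- dQ[keep]
  if (sigma > 0)
    heats <- with_seed(seed, heats + stats::rnorm(length(heats), 0, sigma))
  experiment$heats <- heats
  experiment
}

#' Fit the single-site model to ITC heats
#'
#' Least squares over (Kd, dH, n) on the same forward model as
#' [simulate_itc()], with an optional constant dilution-heat offset
#' (default on). Entropy follows from dG = dH - T dS at the experiment
#' temperature. Non-saturating data (late heats comparable to early ones)
#' raise a wide-confidence-interval warning. Monte-Carlo errors are seeded.
#'
#' @param experiment an [itc_experiment()] with >= 8 retained heats.
#' @param fit_dilution include a constant per-injection offset.
#' @param mc_n Monte-Carlo replicates (default 100; 0 disables).
#' @param seed RNG seed.
#' @return list of class `itc_fit`: `Kd`, `dH`, `n`, `dilution`, `dG`
#'   (kcal/mol), `dS` (kcal/mol/K), sigmas, `saturated` flag.
#' @export
fit_itc_single_site <- function(experiment, fit_dilution = TRUE,
                                mc_n = 100, seed = NULL) {
  y <- experiment$heats
  if (is.null(y) || length(y) < 8) stop("need >= 8 retained injection heats")
  fwd <- function(Kd, dH, n, dil) {
    e2 <- experiment; e2$heats <- NULL
    simulate_itc(binding_model(Kd = Kd, dH = dH, n = n), e2)$heats + dil
  }
  scale0 <- max(abs(y))
  saturated <- mean(abs(utils::tail(y, 3))) < 0.25 * mean(abs(utils::head(y, 3)))
  if (!saturated || scale0 < 10 * stats::sd(diff(y)) / sqrt(2))
    warning("heats do not saturate cleanly; fitted parameters may have wide confidence intervals")
  obj <- function(p) {
    pred <- fwd(exp(p[1]), p[2], exp(p[3]), if (fit_dilution) p[4] else 0)
    sum((y - pred)^2)
  }
  # deterministic starts around the geometry-implied stoichiometry point
  eq_per_inj <- experiment$syringe_conc * experiment$inj_vol[2] /
    (experiment$cell_conc * experiment$V0)
  dH0 <- y[1] / (experiment$syringe_conc * experiment$inj_vol[2] * 1e9)
  starts <- list(
    c(log(experiment$cell_conc / 10), dH0, log(1), 0),
    c(log(experiment$cell_conc), dH0, log(1), 0),
    c(log(experiment$cell_conc / 100), dH0 * 0.8, log(0.8), 0),
    c(log(experiment$cell_conc / 3), dH0 * 1.2, log(1.5), 0)
  )
  best <- NULL
  for (p0 in starts) {
    op <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                                control = list(maxit = 2000, reltol = 1e-12)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("ITC fit failed from all starting points")
  # polish
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  unpack <- function(p) list(Kd = exp(p[1]), dH = p[2], n = exp(p[3]),
                             dil = if (fit_dilution) p[4] else 0)
  est <- unpack(best$par)
  R_kcal <- 1.98720425864083e-3 # kcal mol^-1 K^-1
  dG <- R_kcal * experiment$temperature * log(est$Kd)
  dS <- (est$dH - dG) / experiment$temperature
  kd_sd <- dh_sd <- n_sd <- NA_real_
  if (mc_n > 0) {
    pred <- fwd(est$Kd, est$dH, est$n, est$dil)
    sig <- stats::sd(y - pred)
    if (!is.finite(sig) || sig == 0) sig <- 1e-6 * scale0
    sims <- with_seed(seed, {
      replicate(mc_n, {
        y2 <- pred + stats::rnorm(length(pred), 0, sig)
        o2 <- stats::optim(best$par, function(p) {
          pr <- fwd(exp(p[1]), p[2], exp(p[3]), if (fit_dilution) p[4] else 0)
          sum((y2 - pr)^2)
        }, method = "Nelder-Mead", control = list(maxit = 600))
        u <- unpack(o2$par)
        c(u$Kd, u$dH, u$n)
      })
    })
    kd_sd <- stats::sd(sims[1, ]); dh_sd <- stats::sd(sims[2, ])
    n_sd <- stats::sd(sims[3, ])
  }
  structure(list(Kd = est$Kd, dH = est$dH, n = est$n, dilution = est$dil,
                 dG = dG, dS = dS, Kd_sigma = kd_sd, dH_sigma = dh_sd,
                 n_sigma = n_sd, rss = best$value, saturated = saturated),
            class = "itc_fit")
}
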