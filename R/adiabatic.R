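#' Hyperbolic-secant (HSn) adiabatic spin-lock pulse
#'
#' Amplitude A(t) = w1max * sech(beta * ((2 t / Tp) - 1)^n); the carrier
#' offset sweeps the band \[-bw/2, +bw/2\] as the normalized cumulative
#' integral of A(t)^2. Increasing the stretching factor n flattens the
#' amplitude profile, raising the time-averaged spin-lock field at fixed
#' peak amplitude -- the mechanism that generates relaxation dispersion
#' across HS1 ... HS8.
#'
#' @param n stretching factor (integer >= 1).
#' @param Tp pulse length, s (default 16 ms).
#' @param w1max peak RF amplitude, rad/s (default 2 pi 2.5 kHz).
#' @param bandwidth frequency sweep width, rad/s (default 2 pi 5 kHz).
#' @param npoints waveform discretization (>= 64; default 1024).
#' @param beta truncation parameter, sech(beta) = 1% (default asech(0.01)).
#' @return object of class `adiabatic_pulse` with midpoint-sampled `amp`,
#'   `offset` and `phase` arrays, the step `dt`, and the construction
#'   parameters.
#' @export
build_hs_pulse <- function(n, Tp = 0.016, w1max = 2 * pi * 2500,
                           bandwidth = 2 * pi * 5000, npoints = 1024,
                           beta = acosh(1 / 0.01)) {
  if (n < 1 || n != round(n)) stop("stretching factor n must be an integer >= 1")
  if (Tp <= 0 || w1max <= 0 || bandwidth <= 0) stop("Tp, w1max, bandwidth must be > 0")
  if (npoints < 64) stop("npoints must be >= 64")
  dt <- Tp / npoints
  t <- (seq_len(npoints) - 0.5) * dt        # midpoint sampling
  x <- 2 * t / Tp - 1
  amp <- w1max / cosh(beta * x^n)
  cum <- cumsum(amp^2) - amp^2 / 2          # midpoint cumulative integral
  offset <- -bandwidth / 2 + bandwidth * cum / sum(amp^2)
  phase <- cumsum(offset) * dt
  structure(list(n = n, Tp = Tp, w1max = w1max, bandwidth = bandwidth,
                 npoints = npoints, beta = beta, dt = dt,
                 amp = amp, offset = offset, phase = phase),
            class = "adiabatic_pulse")
}

#' Analytic HSn amplitude A(t)
#' @param pulse an [build_hs_pulse()] object.
#' @param t time(s) in \[0, Tp\], seconds.
#' @return amplitude, rad/s.
#' @export
pulse_amplitude <- function(pulse, t) {
  x <- 2 * t / pulse$Tp - 1
  pulse$w1max / cosh(pulse$beta * x^pulse$n)
}

#' Constant-amplitude spin lock as a degenerate pulse object
#'
#' Utility for oracle tests: a non-swept lock of amplitude `w1` at constant
#' offset `offset`, represented in the same piecewise form as an HSn pulse.
#'
#' @param w1 lock amplitude, rad/s; `offset` constant offset, rad/s.
#' @param offset constant carrier offset, rad/s.
#' @param Tp duration, s; `npoints` discretization.
#' @param npoints number of steps.
#' @return object of class `adiabatic_pulse` (degenerate).
#' @export
constant_lock_pulse <- function(w1, offset = 0, Tp = 0.016, npoints = 64) {
  dt <- Tp / npoints
  structure(list(n = NA, Tp = Tp, w1max = w1, bandwidth = 0,
                 npoints = npoints, beta = NA, dt = dt,
                 amp = rep(w1, npoints), offset = rep(offset, npoints),
                 phase = cumsum(rep(offset, npoints)) * dt),
            class = "adiabatic_pulse")
}

#' Two-state exchange parameters
#'
#' Populations and rate constants obey pA + pB = 1, kAB = pB kex,
#' kBA = (1 - pB) kex (detailed balance pA kAB = pB kBA), with kex =
#' kAB + kBA the exchange rate constant.
#'
#' @param pB excited-state population in (0, 0.5\].
#' @param kex exchange rate constant, s^-1 (>= 0).
#' @param domega ground/excited chemical-shift difference, rad/s.
#' @param R1g,R2g ground-state intrinsic rates, s^-1.
#' @param R1e,R2e excited-state intrinsic rates (default equal to ground:
#'   the standard identifiability constraint).
#' @return object of class `exchange_params`.
#' @export
exchange_params <- function(pB, kex, domega, R1g, R2g,
                            R1e = R1g, R2e = R2g) {
  if (pB <= 0 || pB > 0.5) stop("pB must lie in (0, 0.5]")
  if (kex < 0) stop("kex must be >= 0")
  if (R1g < 0 || R2g < 0 || R1e < 0 || R2e < 0) stop("rates must be >= 0")
  structure(list(pB = pB, pA = 1 - pB, kex = kex,
                 kab = pB * kex, kba = (1 - pB) * kex,
                 domega = domega, R1g = R1g, R2g = R2g,
                 R1e = R1e, R2e = R2e),
            class = "exchange_params")
}

# 6-vector initial magnetization along a unit axis, split by populations
.bm_initial <- function(model, axis) {
  axis <- axis / sqrt(sum(axis^2))
  c(model$pA * axis, model$pB * axis)
}

#' Propagate two-state magnetization through a spin-lock pulse train
#'
#' Applies the 6x6 Bloch-McConnell propagator of `pulse` (computed once by a
#' piecewise-constant matrix-exponential, compiled) `n_pulses` times and
#' records the magnetization at every pulse boundary.
#'
#' @param model an [exchange_params()].
#' @param pulse an [build_hs_pulse()] / [constant_lock_pulse()] object.
#' @param M0 initial magnetization: a 6-vector (Ax, Ay, Az, Bx, By, Bz) or a
#'   3-vector axis that is split across states by population.
#' @param n_pulses number of pulse repetitions (>= 1).
#' @param check_step if TRUE, re-propagate with a coarser (halved) waveform
#'   and raise an error when the final magnetization differs by more than
#'   `step_tol` relative -- a failed convergence-doubling test indicating
#'   that `npoints` is too small.
#' @param step_tol tolerance for the doubling test (default 1e-4).
#' @return matrix (n_pulses + 1) x 6 of magnetization at pulse boundaries.
#' @export
bm_propagate <- function(model, pulse, M0 = c(0, 0, 1), n_pulses = 1,
                         check_step = FALSE, step_tol = 1e-4) {
  stopifnot(inherits(model, "exchange_params"),
            inherits(pulse, "adiabatic_pulse"), n_pulses >= 1)
  if (length(M0) == 3) M0 <- .bm_initial(model, M0)
  stopifnot(length(M0) == 6)
  U <- bm_pulse_propagator(model$R1g, model$R2g, model$R1e, model$R2e,
                           model$kab, model$kba, model$domega,
                           pulse$amp, pulse$offset, pulse$dt)
  out <- matrix(NA_real_, n_pulses + 1, 6)
  out[1, ] <- M0
  M <- M0
  for (k in seq_len(n_pulses)) {
    M <- as.numeric(U %*% M)
    out[k + 1, ] <- M
  }
  if (check_step) {
    half <- seq(1, pulse$npoints, by = 2)
    U2 <- bm_pulse_propagator(model$R1g, model$R2g, model$R1e, model$R2e,
                              model$kab, model$kba, model$domega,
                              (pulse$amp[half] + pulse$amp[half + 1]) / 2,
                              (pulse$offset[half] + pulse$offset[half + 1]) / 2,
                              pulse$dt * 2)
    M2 <- M0
    for (k in seq_len(n_pulses)) M2 <- as.numeric(U2 %*% M2)
    ref <- max(sqrt(sum(M^2)), 1e-12)
    if (sqrt(sum((M - M2)^2)) / ref > step_tol)
      stop("waveform step-doubling test failed; increase npoints")
  }
  out
}

# ideal (relaxation- and exchange-free) rotation of a unit axis over pulses:
# reference trajectory for projecting the measured magnetization
.ideal_axes <- function(pulse, axis, n_pulses) {
  U <- bm_pulse_propagator(0, 0, 0, 0, 0, 0, 0, pulse$amp, pulse$offset,
                           pulse$dt)[1:3, 1:3]
  out <- matrix(NA_real_, n_pulses + 1, 3)
  e <- axis / sqrt(sum(axis^2))
  out[1, ] <- e
  for (k in seq_len(n_pulses)) {
    e <- as.numeric(U %*% e)
    e <- e / sqrt(sum(e^2))
    out[k + 1, ] <- e
  }
  out
}

# model-independent per-pulse cache: ideal axis trajectories for the z- and
# x-started experiments, reused across the many forward evaluations a fit
# makes
.hard_cache <- function(pulses, kmax1, kmax2) {
  lapply(pulses, function(p)
    list(ax_z = .ideal_axes(p, c(0, 0, 1), kmax1),
         ax_x = .ideal_axes(p, c(1, 0, 0), kmax2)))
}

# fast deterministic mono-exponential fit for clean positive decays:
# log-linear start + Gauss-Newton polishing (signals from the BM forward
# model are noiseless, so a few iterations converge to machine precision)
.fit_monoexp_fast <- function(t, y) {
  if (any(y <= 0)) return(.fit_monoexp_xy(t, y)$rate)
  cf <- stats::lsfit(t, log(y))$coefficients
  I0 <- exp(cf[1]); R <- -cf[2]
  for (i in 1:6) {
    mu <- I0 * exp(-R * t)
    Jm <- cbind(mu / I0, -t * mu)
    r <- y - mu
    d <- tryCatch(solve(crossprod(Jm), crossprod(Jm, r)),
                  error = function(e) matrix(0, 2, 1))
    I0 <- I0 + d[1]; R <- R + d[2]
    if (!is.finite(I0) || !is.finite(R)) return(.fit_monoexp_xy(t, y)$rate)
  }
  R
}

#' Simulate HARD rotating-frame rates for one residue
#'
#' For each HSn pulse, propagates the two-state Bloch-McConnell equations
#' through the spin-lock train, projects the total magnetization onto the
#' ideally rotated initial axis at each delay (an integer number of pulses),
#' and extracts R1rho (start along +z) and R2rho (start along +x) by
#' mono-exponential fits of signal versus delay.
#'
#' @param model an [exchange_params()].
#' @param pulses named list of [build_hs_pulse()] objects (e.g. HS1..HS8).
#' @param delays_r1rho,delays_r2rho relaxation delays, s, integer multiples
#'   of Tp (defaults: 0/16/32/64/96/128 ms and 0/16/32/64 ms).
#' @return list of class `hard_row`: `R1` (= R1g), named vectors `R1rho`,
#'   `R2rho`.
#' @export
simulate_hard_rates <- function(model, pulses,
                                delays_r1rho = c(0, 16, 32, 64, 96, 128) / 1000,
                                delays_r2rho = c(0, 16, 32, 64) / 1000,
                                .cache = NULL) {
  ks1 <- delays_r1rho / pulses[[1]]$Tp
  ks2 <- delays_r2rho / pulses[[1]]$Tp
  if (any(abs(c(ks1, ks2) - round(c(ks1, ks2))) > 1e-9))
    stop("relaxation delays must be integer multiples of the pulse length Tp")
  ks1 <- round(ks1); ks2 <- round(ks2)
  kmax <- max(ks1, ks2, 1)
  if (is.null(.cache)) .cache <- .hard_cache(pulses, max(ks1, 1), max(ks2, 1))
  r1rho <- r2rho <- numeric(length(pulses))
  for (i in seq_along(pulses)) {
    p <- pulses[[i]]
    U <- bm_pulse_propagator(model$R1g, model$R2g, model$R1e, model$R2e,
                             model$kab, model$kba, model$domega,
                             p$amp, p$offset, p$dt)
    Mz <- .bm_initial(model, c(0, 0, 1))
    Mx <- .bm_initial(model, c(1, 0, 0))
    sig_z <- numeric(kmax + 1); sig_x <- numeric(kmax + 1)
    ax_z <- .cache[[i]]$ax_z; ax_x <- .cache[[i]]$ax_x
    sig_z[1] <- 1; sig_x[1] <- 1
    for (k in seq_len(kmax)) {
      Mz <- as.numeric(U %*% Mz); Mx <- as.numeric(U %*% Mx)
      if (k + 1 <= nrow(ax_z))
        sig_z[k + 1] <- sum((Mz[1:3] + Mz[4:6]) * ax_z[k + 1, ])
      if (k + 1 <= nrow(ax_x))
        sig_x[k + 1] <- sum((Mx[1:3] + Mx[4:6]) * ax_x[k + 1, ])
    }
    r1rho[i] <- .fit_monoexp_fast(delays_r1rho, sig_z[ks1 + 1])
    r2rho[i] <- .fit_monoexp_fast(delays_r2rho, sig_x[ks2 + 1])
  }
  names(r1rho) <- names(r2rho) <- names(pulses)
  structure(list(R1 = model$R1g, R1rho = r1rho, R2rho = r2rho),
            class = "hard_row")
}

#' Standard HSn pulse set
#' @param ns stretching factors (default c(1, 2, 4, 6, 8)).
#' @param ... passed to [build_hs_pulse()].
#' @return named list of pulses ("HS1", "HS2", ...).
#' @export
hs_pulse_set <- function(ns = c(1, 2, 4, 6, 8), ...) {
  out <- lapply(ns, build_hs_pulse, ...)
  names(out) <- paste0("HS", ns)
  out
}

#' Fit the two-state exchange model to HARD dispersion data
#'
#' Coarse grid search in (log10 kex, pB, domega) -- with the ground-state R2
#' anchored near the smallest observed R2rho -- followed by local
#' least-squares refinement of (pB, kex, domega, R2g) against the forward
#' simulation ([simulate_hard_rates()]). R1g is fixed by the measured R1.
#' A "no detectable exchange" sentinel is returned instead of arbitrary
#' parameters when the data carry no exchange information: either the raw
#' profiles are flat (dispersion below `flat_k` times the noise) or the
#' exchange-free baseline model -- whose rates still vary with HSn because
#' the tilt-angle trajectory does -- already reproduces the data within
#' noise. Parameter uncertainties come from seeded Monte-Carlo refits.
#'
#' @param row list with `R1`, `R1rho`, `R2rho` (named by HSn) as produced by
#'   [simulate_hard_rates()] plus noise.
#' @param pulses the HSn pulse list used in acquisition.
#' @param sigma rate noise, s^-1 (scalar or per-observable); default 2% of
#'   the median rate.
#' @param delays_r1rho,delays_r2rho delays used in the forward model.
#' @param field proton frequency (MHz) used to convert domega between ppm
#'   and rad/s (15N ppm scale).
#' @param grid list with `kex` (log10 range + length), `pB`, `dw_ppm`
#'   ranges; default 12 x 10 x 8 as documented.
#' @param mc_n Monte-Carlo replicates for errors (default 500; 0 disables).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @param flat_k flatness threshold multiplier (default 2).
#' @param fix_dw fix the state shift difference at this value (ppm) instead
#'   of fitting it. With a single field and a handful of HSn conditions,
#'   (pB, kex, domega) trade off against each other; supplying domega (e.g.
#'   from observed shift differences) restores identifiability of pB and
#'   kex.
#' @param fix_r2g fix the ground-state intrinsic R2 at this value (s^-1)
#'   instead of fitting it; used together with `fix_dw` in parameter
#'   recovery studies, where the remaining (pB, kex) pair is identifiable.
#' @param fix_pb fix the excited-state population instead of fitting it. In
#'   the very fast regime (kex far above the attainable spin-lock field)
#'   only the quotient pB (1 - pB) / kex is constrained by the data, so kex
#'   recovery additionally requires a known pB.
#' @return object of class `exchange_fit`: either
#'   `list(no_exchange = TRUE, ...)` or fitted `pB`, `kex`, `dw_ppm`,
#'   `R2g`, `rss`, and `kex_sigma` / `pB_sigma` when `mc_n > 0`.
#' @export
fit_two_state <- function(row, pulses, sigma = NULL,
                          delays_r1rho = c(0, 16, 32, 64, 96, 128) / 1000,
                          delays_r2rho = c(0, 16, 32, 64) / 1000,
                          field = 600,
                          grid = list(kex = c(2, 6, 12), pB = c(0.01, 0.5, 10),
                                      dw_ppm = c(0.2, 6, 8)),
                          mc_n = 500, seed = NULL, flat_k = 2,
                          fix_dw = NULL, fix_r2g = NULL, fix_pb = NULL) {
  if (length(row$R1rho) < 3) stop("need >= 3 HSn conditions")
  y <- c(row$R1rho, row$R2rho)
  if (is.null(sigma)) sigma <- 0.02 * stats::median(y)
  sig <- rep(sigma, length.out = length(y))
  disp <- max(diff(range(row$R1rho)), diff(range(row$R2rho)))
  if (disp < flat_k * stats::median(sig))
    return(structure(list(no_exchange = TRUE, dispersion = disp,
                          noise = stats::median(sig)),
                     class = "exchange_fit"))
  ctx <- spectrometer_context(field)
  ppm2rad <- abs(ctx$omegaN) * 1e-6
  cache <- .hard_cache(pulses, max(round(delays_r1rho / pulses[[1]]$Tp), 1),
                       max(round(delays_r2rho / pulses[[1]]$Tp), 1))
  forward <- function(pB, kex, dw_ppm, R2g) {
    m <- exchange_params(pB = pB, kex = kex, domega = dw_ppm * ppm2rad,
                         R1g = row$R1, R2g = R2g)
    s <- simulate_hard_rates(m, pulses, delays_r1rho, delays_r2rho,
                             .cache = cache)
    c(s$R1rho, s$R2rho)
  }
  # exchange-free baseline (tilt-angle dispersion only): if it already fits
  # within noise, the data carry no exchange information. A known intrinsic
  # R2 (fix_r2g) anchors the baseline, so uniformly elevated rates -- the
  # signature of very fast exchange -- are not absorbed into it.
  base <- if (is.null(fix_r2g)) {
    stats::optimize(function(R2g)
      sum(((y - forward(0.01, 0, 1, R2g)) / sig)^2),
      interval = c(max(row$R1, 0.1), 2 * max(row$R2rho)), tol = 1e-6)
  } else {
    list(minimum = fix_r2g,
         objective = sum(((y - forward(0.01, 0, 1, fix_r2g)) / sig)^2))
  }
  if (base$objective <= stats::qchisq(0.995, length(y) - 1))
    return(structure(list(no_exchange = TRUE, dispersion = disp,
                          noise = stats::median(sig),
                          baseline_chisq = base$objective,
                          R2g = base$minimum),
                     class = "exchange_fit"))
  # bounded internal parameterization: kex log-uniform in [10^lo, 10^hi],
  # pB and domega logistic inside their bounds, R2g log-positive
  kr <- grid$kex[1:2]; pr <- grid$pB[1:2]; dr <- grid$dw_ppm[1:2]
  tr <- function(p) {
    i <- 1
    kex <- 10^(kr[1] + diff(kr) * stats::plogis(p[i])); i <- i + 1
    pB <- if (is.null(fix_pb)) {
      v <- pr[1] + diff(pr) * stats::plogis(p[i]); i <- i + 1; v
    } else fix_pb
    dw <- if (is.null(fix_dw)) {
      v <- dr[1] + diff(dr) * stats::plogis(p[i]); i <- i + 1; v
    } else fix_dw
    R2g <- if (is.null(fix_r2g)) exp(p[i]) else fix_r2g
    list(kex = kex, pB = pB, dw_ppm = dw, R2g = R2g)
  }
  inv <- function(kex, pB, dw, R2g) {
    sq <- function(x) stats::qlogis(pmin(pmax(x, 0.02), 0.98))
    c(sq((log10(kex) - kr[1]) / diff(kr)),
      if (is.null(fix_pb)) sq((pB - pr[1]) / diff(pr)),
      if (is.null(fix_dw)) sq((dw - dr[1]) / diff(dr)),
      if (is.null(fix_r2g)) log(R2g))
  }
  obj_for <- function(ydat) function(p) {
    v <- tr(p)
    pred <- tryCatch(forward(v$pB, v$kex, v$dw_ppm, v$R2g),
                     error = function(e) NULL)
    if (is.null(pred)) return(1e12)
    sum(((ydat - pred) / sig)^2)
  }
  obj <- obj_for(y)
  R2g0 <- max(0.9 * min(row$R2rho), row$R1, 0.5)
  kex_g <- seq(kr[1], kr[2], length.out = grid$kex[3])
  pB_g <- if (is.null(fix_pb)) seq(pr[1], pr[2], length.out = grid$pB[3])
          else fix_pb
  dw_g <- if (is.null(fix_dw)) seq(dr[1], dr[2], length.out = grid$dw_ppm[3])
          else fix_dw
  cand <- list()
  for (lk in kex_g) for (pb in pB_g) for (dw in dw_g) {
    p <- inv(10^lk, pb, dw, R2g0)
    cand[[length(cand) + 1]] <- list(p = p, v = obj(p))
  }
  cand <- cand[order(vapply(cand, `[[`, 0, "v"))]
  refine <- function(p0, objfun, maxit = 500) {
    if (length(p0) == 1)
      stats::optim(p0, objfun, method = "Brent", lower = -20, upper = 20)
    else
      stats::optim(p0, objfun, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
  }
  op <- NULL
  for (st in cand[seq_len(min(3, length(cand)))]) {
    o <- refine(st$p, obj)
    if (is.null(op) || o$value < op$value) op <- o
  }
  est <- tr(op$par)
  kex_sd <- pB_sd <- NA_real_
  if (mc_n > 0) {
    pred <- forward(est$pB, est$kex, est$dw_ppm, est$R2g)
    sims <- with_seed(seed, {
      replicate(mc_n, {
        y2 <- pred + stats::rnorm(length(pred), 0, sig)
        o2 <- refine(op$par, obj_for(y2), maxit = 200)
        u <- tr(o2$par)
        c(u$kex, u$pB)
      })
    })
    kex_sd <- stats::sd(sims[1, ]); pB_sd <- stats::sd(sims[2, ])
  }
  structure(list(no_exchange = FALSE, pB = est$pB, kex = est$kex,
                 dw_ppm = est$dw_ppm, R2g = est$R2g, R1g = row$R1,
                 rss = op$value, kex_sigma = kex_sd, pB_sigma = pB_sd),
            class = "exchange_fit")
}

#' Classify fitted exchange parameters
#'
#' kex bins: slow (< 5000 s^-1), fast (5000 - 50,000), very_fast
#' (> 50,000); pB bins: "<10%", "10-20%", "20-40%", ">40%". A no-exchange
#' sentinel classifies as "none".
#'
#' @param fit an [fit_two_state()] result.
#' @param kex_bins kex bin edges, s^-1 (default c(5000, 50000)).
#' @param pb_bins pB bin edges (default c(0.1, 0.2, 0.4)).
#' @return list: `kex_class`, `pb_class`.
#' @export
classify_exchange <- function(fit, kex_bins = c(5000, 50000),
                              pb_bins = c(0.1, 0.2, 0.4)) {
  if (isTRUE(fit$no_exchange))
    return(list(kex_class = "none", pb_class = "none"))
  kex_class <- if (fit$kex < kex_bins[1]) "slow"
               else if (fit$kex <= kex_bins[2]) "fast" else "very_fast"
  pb_class <- if (fit$pB < pb_bins[1]) "<10%"
              else if (fit$pB < pb_bins[2]) "10-20%"
              else if (fit$pB < pb_bins[3]) "20-40%" else ">40%"
  list(kex_class = kex_class, pb_class = pb_class)
}

#' Apo-versus-bound exchange-rate differences
#'
#' Delta kex = kex(bound) - kex(apo) per residue, flagged when |Delta kex|
#' exceeds `threshold` (default 10,000 s^-1), with the sign recorded as
#' "induced" (positive) or "quenched" (negative). Residues present in only
#' one state are emitted with a missing-state marker.
#'
#' @param apo_fits,bound_fits named lists of [fit_two_state()] results
#'   (names = residue numbers).
#' @param threshold flag threshold, s^-1.
#' @return data.frame: `residue`, `kex_apo`, `kex_bound`, `delta_kex`,
#'   `flagged`, `direction`, `missing_state`.
#' @export
delta_kex <- function(apo_fits, bound_fits, threshold = 10000) {
  res <- sort(unique(as.integer(c(names(apo_fits), names(bound_fits)))))
  get_kex <- function(fits, r) {
    f <- fits[[as.character(r)]]
    if (is.null(f) || isTRUE(f$no_exchange)) NA_real_ else f$kex
  }
  rows <- lapply(res, function(r) {
    ka <- get_kex(apo_fits, r); kb <- get_kex(bound_fits, r)
    miss <- if (is.null(apo_fits[[as.character(r)]])) "apo"
            else if (is.null(bound_fits[[as.character(r)]])) "bound"
            else NA_character_
    d <- kb - ka
    data.frame(residue = r, kex_apo = ka, kex_bound = kb, delta_kex = d,
               flagged = !is.na(d) && abs(d) > threshold,
               direction = if (is.na(d)) NA_character_
                           else if (d > 0) "induced" else "quenched",
               missing_state = miss)
  })
  do.call(rbind, rows)
}
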