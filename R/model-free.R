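#' Extended Lipari-Szabo model-free parameters
#'
#' Internal N-H vector dynamics are described by a fast-motion order
#' parameter `Sf2`, a generalized order parameter `S2` (0 <= S2 <= Sf2 <= 1),
#' internal correlation times `tf` (fast) and `ts` (slow, the "tau_e" of the
#' simple models), and an exchange broadening `Rex` (s^-1) referenced to
#' `ref_mhz` and scaled quadratically with the field when predicting R2.
#'
#' Model ladder (conventional): m0 rigid; m1 \{S2\}; m2 \{S2, ts\};
#' m3 \{S2, Rex\}; m4 \{S2, ts, Rex\}; m5 \{Sf2, S2, ts\};
#' m6 \{Sf2, tf, S2, ts\}; m7 \{Sf2, S2, ts, Rex\};
#' m8 \{Sf2, tf, S2, ts, Rex\}. With `tf = 0` the spectral density reduces
#' to the two-timescale extended form, and with `Sf2 = 1` to the original
#' Lipari-Szabo form.
#'
#' @param S2 generalized order parameter in \[0, 1\].
#' @param Sf2 fast-motion order parameter, S2 <= Sf2 <= 1.
#' @param tf,ts internal correlation times, seconds (>= 0).
#' @param Rex exchange broadening at the reference field, s^-1 (>= 0).
#' @param model_id model label (m0..m8), bookkeeping only.
#' @param ref_mhz reference 1H frequency for Rex, MHz.
#' @return object of class `modelfree_params`.
#' @export
modelfree_params <- function(S2, Sf2 = 1, tf = 0, ts = 0, Rex = 0,
                             model_id = NA_character_, ref_mhz = 600) {
  if (S2 < 0 || S2 > 1 || Sf2 < 0 || Sf2 > 1 || S2 > Sf2 + 1e-12)
    stop("require 0 <= S2 <= Sf2 <= 1")
  if (tf < 0 || ts < 0 || Rex < 0) stop("tf, ts, Rex must be >= 0")
  structure(list(S2 = S2, Sf2 = Sf2, tf = tf, ts = ts, Rex = Rex,
                 model_id = model_id, ref_mhz = ref_mhz),
            class = "modelfree_params")
}

#' Global rotational diffusion model
#'
#' @param kind `"isotropic"` or `"axially_symmetric"`.
#' @param tc global rotational correlation time, s (tc = 1/(6 Diso)).
#' @param ratio Dpar/Dperp anisotropy ratio (> 0; 1 = isotropic).
#' @param theta,phi polar angles (rad) of the unique diffusion axis.
#' @return object of class `diffusion_model`.
#' @export
diffusion_model <- function(kind = c("isotropic", "axially_symmetric"),
                            tc, ratio = 1, theta = 0, phi = 0) {
  kind <- match.arg(kind)
  stopifnot(tc > 0, ratio > 0)
  structure(list(kind = kind, tc = tc, ratio = ratio,
                 theta = theta, phi = phi),
            class = "diffusion_model")
}

# correlation times and weights of the global motion seen by an N-H vector.
# isotropic: one time tc with weight 1. axially symmetric: three times from
# (Dpar, Dperp) with weights depending on the angle alpha between the N-H
# vector and the symmetry axis.
.diffusion_components <- function(diffusion, vec = NULL) {
  if (diffusion$kind == "isotropic" || abs(diffusion$ratio - 1) < 1e-12)
    return(list(tau = diffusion$tc, A = 1))
  if (is.null(vec)) stop("axially symmetric diffusion needs an N-H unit vector")
  Diso <- 1 / (6 * diffusion$tc)
  # Diso = (Dpar + 2 Dperp) / 3, ratio = Dpar / Dperp
  Dperp <- 3 * Diso / (diffusion$ratio + 2)
  Dpar <- diffusion$ratio * Dperp
  ax <- c(sin(diffusion$theta) * cos(diffusion$phi),
          sin(diffusion$theta) * sin(diffusion$phi),
          cos(diffusion$theta))
  ca <- sum(vec * ax) / sqrt(sum(vec^2))
  ca2 <- ca^2
  tau <- c(1 / (6 * Dperp),
           1 / (5 * Dperp + Dpar),
           1 / (2 * Dperp + 4 * Dpar))
  A <- c((1.5 * ca2 - 0.5)^2, 3 * ca2 * (1 - ca2), 0.75 * (1 - ca2)^2)
  list(tau = tau, A = A)
}

#' Model-free spectral density J(omega)
#'
#' J(w) = (2/5) sum_j A_j \[ S2 tau_j/(1+(w tau_j)^2)
#'        + (1 - Sf2) tf'_j/(1+(w tf'_j)^2)
#'        + (Sf2 - S2) ts'_j/(1+(w ts'_j)^2) \],
#' with 1/t'_j = 1/tau_j + 1/t. For isotropic tumbling there is a single
#' global time tau_c (A = 1); `Sf2 = 1, tf = 0` recovers the original
#' Lipari-Szabo form. Units: s/rad.
#'
#' @param params [modelfree_params()].
#' @param diffusion [diffusion_model()].
#' @param omega angular frequency (rad/s), vectorized, >= 0.
#' @param vec N-H unit vector (length 3), required for axially symmetric
#'   diffusion.
#' @return J(omega), same length as `omega`.
#' @export
spectral_density <- function(params, diffusion, omega, vec = NULL) {
  comp <- .diffusion_components(diffusion, vec)
  out <- numeric(length(omega))
  for (j in seq_along(comp$tau)) {
    tau <- comp$tau[j]
    term <- params$S2 * tau / (1 + (omega * tau)^2)
    if (params$Sf2 < 1 && params$tf > 0) {
      tfp <- 1 / (1 / tau + 1 / params$tf)
      term <- term + (1 - params$Sf2) * tfp / (1 + (omega * tfp)^2)
    }
    if (params$Sf2 - params$S2 > 0 && params$ts > 0) {
      tsp <- 1 / (1 / tau + 1 / params$ts)
      term <- term + (params$Sf2 - params$S2) * tsp / (1 + (omega * tsp)^2)
    }
    out <- out + comp$A[j] * term
  }
  0.4 * out
}

#' Predict R1, R2 and heteronuclear nOe from model-free parameters
#'
#' Standard dipolar + CSA expressions for an amide 15N spin:
#' R1 = (d^2/4)\[J(wH-wN) + 3 J(wN) + 6 J(wH+wN)\] + c^2 J(wN);
#' R2 = (d^2/8)\[4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)\]
#'      + (c^2/6)\[4 J(0) + 3 J(wN)\] + Rex (B/Bref)^2;
#' nOe = 1 + (d^2/4)(gammaH/gammaN)\[6 J(wH+wN) - J(wH-wN)\]/R1.
#' Frequencies are used by magnitude (gammaN < 0).
#'
#' @param params [modelfree_params()].
#' @param diffusion [diffusion_model()].
#' @param context [spectrometer_context()].
#' @param constants [nmr_constants()].
#' @param vec optional N-H unit vector (axial diffusion).
#' @return list: `R1`, `R2`, `nOe` (R1/R2 in s^-1).
#' @export
predict_relaxation <- function(params, diffusion, context,
                               constants = nmr_constants(), vec = NULL) {
  wH <- abs(context$omegaH); wN <- abs(context$omegaN)
  d <- dipolar_constant(constants)
  cc <- csa_constant(wN, constants)
  J <- function(w) spectral_density(params, diffusion, w, vec)
  JhmN <- J(wH - wN); JN <- J(wN); JhpN <- J(wH + wN)
  J0 <- J(0); Jh <- J(wH)
  R1 <- (d^2 / 4) * (JhmN + 3 * JN + 6 * JhpN) + cc^2 * JN
  rex <- params$Rex * (context$proton_mhz / params$ref_mhz)^2
  R2 <- (d^2 / 8) * (4 * J0 + JhmN + 3 * JN + 6 * Jh + 6 * JhpN) +
        (cc^2 / 6) * (4 * J0 + 3 * JN) + rex
  nOe <- 1 + (d^2 / 4) * (constants$gammaH / constants$gammaN) *
    (6 * JhpN - JhmN) / R1
  list(R1 = R1, R2 = R2, nOe = nOe)
}

#' Initial estimate of tau_c from the R2/R1 ratio of rigid residues
#'
#' Takes the trimmed mean of R2/R1 over residues whose nOe exceeds
#' `noe_cutoff` (rigid candidates) inside `window`, then solves the
#' rigid-limit (S2 = 1, no internal motion, no exchange) ratio for tau_c by
#' a one-dimensional root search.
#'
#' @param table a [rate_table()] holding R1, R2 and nOe rows at `field`.
#' @param window inclusive residue range.
#' @param field spectrometer field, MHz.
#' @param state "apo" or "bound".
#' @param noe_cutoff rigid-candidate nOe threshold (default 0.65).
#' @param trim trimmed-mean fraction (default 0.1).
#' @param min_rigid minimum number of rigid candidates (default 5).
#' @param constants [nmr_constants()].
#' @return tau_c in seconds.
#' @export
estimate_tc_from_r2r1 <- function(table, window, field = 600, state = "apo",
                                  noe_cutoff = 0.65, trim = 0.1,
                                  min_rigid = 5,
                                  constants = nmr_constants()) {
  r1 <- filter_rates(table, kind = "R1", field = field, state = state,
                     window = window)
  r2 <- filter_rates(table, kind = "R2", field = field, state = state,
                     window = window)
  noe <- filter_rates(table, kind = "nOe", field = field, state = state,
                      window = window)
  rigid <- noe$residue[noe$value > noe_cutoff]
  common <- intersect(intersect(r1$residue, r2$residue), rigid)
  if (length(common) < min_rigid)
    stop(sprintf("only %d rigid-candidate residues (nOe > %g); need >= %d",
                 length(common), noe_cutoff, min_rigid))
  ratio <- vapply(common, function(r)
    r2$value[r2$residue == r] / r1$value[r1$residue == r], numeric(1))
  target <- mean(ratio, trim = trim)
  ratio_tc(target, field, constants)
}

# solve rigid-limit R2/R1 = target for tau_c
ratio_tc <- function(target, field, constants = nmr_constants()) {
  ctx <- spectrometer_context(field, constants = constants)
  rigid <- modelfree_params(S2 = 1)
  f <- function(tc) {
    p <- predict_relaxation(rigid, diffusion_model("isotropic", tc = tc),
                            ctx, constants)
    p$R2 / p$R1 - target
  }
  stats::uniroot(f, interval = c(0.2e-9, 100e-9), tol = 1e-14)$root
}

# model ladder: free parameters of each model
.mf_models <- list(
  m0 = character(0),
  m1 = c("S2"),
  m2 = c("S2", "ts"),
  m3 = c("S2", "Rex"),
  m4 = c("S2", "ts", "Rex"),
  m5 = c("Sf2", "S2", "ts"),
  m6 = c("Sf2", "tf", "S2", "ts"),
  m7 = c("Sf2", "S2", "ts", "Rex"),
  m8 = c("Sf2", "tf", "S2", "ts", "Rex")
)

# pack/unpack: internal optimizer vector is on transformed scales --
# order parameters as-is in [0,1] (S2 expressed as a fraction of Sf2 so the
# ordering constraint is structural), taus in ns, Rex in s^-1.
.mf_build_params <- function(model, x, ref_mhz) {
  free <- .mf_models[[model]]
  v <- list(Sf2 = 1, frac = 1, tf = 0, ts = 0, Rex = 0)
  i <- 1
  for (nm in free) {
    if (nm == "S2") { v$frac <- x[i] } else if (nm == "Sf2") { v$Sf2 <- x[i] }
    else if (nm == "tf") { v$tf <- x[i] * 1e-9 }
    else if (nm == "ts") { v$ts <- x[i] * 1e-9 }
    else if (nm == "Rex") { v$Rex <- x[i] }
    i <- i + 1
  }
  modelfree_params(S2 = v$Sf2 * v$frac, Sf2 = v$Sf2, tf = v$tf, ts = v$ts,
                   Rex = v$Rex, model_id = model, ref_mhz = ref_mhz)
}

.mf_bounds <- function(model) {
  free <- .mf_models[[model]]
  lo <- c(S2 = 0, Sf2 = 0, tf = 0, ts = 0, Rex = 0)
  hi <- c(S2 = 1, Sf2 = 1, tf = 0.5, ts = 10, Rex = 50) # taus in ns
  list(lower = unname(lo[free]), upper = unname(hi[free]))
}

# five deterministic starting points per model
.mf_starts <- function(model) {
  free <- .mf_models[[model]]
  base <- list(
    c(S2 = 0.85, Sf2 = 0.95, tf = 0.01, ts = 0.05, Rex = 0.5),
    c(S2 = 0.95, Sf2 = 1.00, tf = 0.02, ts = 0.50, Rex = 2.0),
    c(S2 = 0.60, Sf2 = 0.90, tf = 0.05, ts = 1.50, Rex = 5.0),
    c(S2 = 0.35, Sf2 = 0.80, tf = 0.10, ts = 3.00, Rex = 10.0),
    c(S2 = 0.75, Sf2 = 0.85, tf = 0.005, ts = 0.02, Rex = 0.1)
  )
  lapply(base, function(b) unname(b[free]))
}

#' Fit model-free parameters for one residue with model selection
#'
#' Minimizes chi^2 = sum((obs - pred)/sigma)^2 over R1/R2/nOe observables
#' at one or two fields for each model in `models`, from five deterministic
#' starting points per model, with the global diffusion fixed. The best
#' model is chosen by small-sample corrected AIC by default (AICc =
#' chi^2 + 2k + 2k(k+1)/(n-k-1); with 3-6 observables per residue the
#' correction matters and plain AIC systematically overfits); ties go to
#' the model with fewer parameters. Models with too many parameters for the
#' observation count are penalized to infinity, i.e. never selected.
#'
#' @param obs data.frame with columns `kind` (R1/R2/nOe), `field` (MHz),
#'   `value`, `sigma`; >= 3 rows.
#' @param diffusion a fixed [diffusion_model()].
#' @param models character vector of model ids to try (default the full
#'   ladder m0..m8).
#' @param constants [nmr_constants()].
#' @param ref_mhz Rex reference field, MHz.
#' @param vec optional N-H unit vector (axial diffusion).
#' @param criterion `"aicc"` (default) or `"aic"`.
#' @return list of class `modelfree_fit`: `params` (best
#'   [modelfree_params()]), `chisq`, `aic`, `model_table` (per-model chi^2 /
#'   AIC / AICc / k), `n_obs`.
#' @export
fit_modelfree_residue <- function(obs, diffusion,
                                  models = names(.mf_models),
                                  constants = nmr_constants(),
                                  ref_mhz = 600, vec = NULL,
                                  criterion = c("aicc", "aic")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(obs) >= 3)
  bad <- setdiff(models, names(.mf_models))
  if (length(bad)) stop("unknown model id: ", paste(bad, collapse = ", "))
  fields <- sort(unique(obs$field))
  ctxs <- lapply(fields, spectrometer_context, constants = constants)
  names(ctxs) <- as.character(fields)
  sig <- ifelse(is.finite(obs$sigma) & obs$sigma > 0, obs$sigma,
                pmax(abs(obs$value) * 0.02, 1e-6))
  chisq_of <- function(params) {
    tot <- 0
    for (f in fields) {
      pred <- predict_relaxation(params, diffusion, ctxs[[as.character(f)]],
                                 constants, vec)
      rows <- which(obs$field == f)
      for (r in rows) {
        p <- switch(obs$kind[r], R1 = pred$R1, R2 = pred$R2, nOe = pred$nOe,
                    stop("model-free fit accepts R1/R2/nOe observables"))
        tot <- tot + ((obs$value[r] - p) / sig[r])^2
      }
    }
    tot
  }
  results <- list()
  for (m in models) {
    k <- length(.mf_models[[m]])
    if (k == 0) {
      ch <- chisq_of(.mf_build_params(m, numeric(0), ref_mhz))
      results[[m]] <- list(params = .mf_build_params(m, numeric(0), ref_mhz),
                           chisq = ch, k = 0, aic = ch)
      next
    }
    b <- .mf_bounds(m)
    best <- NULL
    for (x0 in .mf_starts(m)) {
      op <- tryCatch(
        stats::optim(x0, function(x) chisq_of(.mf_build_params(m, x, ref_mhz)),
                     method = "L-BFGS-B", lower = b$lower, upper = b$upper,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) next
    results[[m]] <- list(params = .mf_build_params(m, best$par, ref_mhz),
                         chisq = best$value, k = k, aic = best$value + 2 * k)
  }
  if (!length(results))
    stop("optimizer failed for every model; per-model diagnostics unavailable")
  tab <- data.frame(model = names(results),
                    k = vapply(results, `[[`, 0, "k"),
                    chisq = vapply(results, `[[`, 0, "chisq"),
                    aic = vapply(results, `[[`, 0, "aic"))
  n <- nrow(obs)
  tab$aicc <- tab$chisq + 2 * tab$k +
    ifelse(n - tab$k - 1 > 0, 2 * tab$k * (tab$k + 1) / (n - tab$k - 1), Inf)
  crit <- if (criterion == "aicc") tab$aicc else tab$aic
  # ties (within 1e-6) broken toward fewer parameters: sort by (k, model)
  o <- order(tab$k, tab$model)
  tab <- tab[o, ]; crit <- crit[o]
  best_m <- tab$model[which(crit <= min(crit) + 1e-6)[1]]
  structure(list(params = results[[best_m]]$params,
                 chisq = results[[best_m]]$chisq,
                 aic = results[[best_m]]$aic,
                 model_table = tab[order(if (criterion == "aicc") tab$aicc
                                         else tab$aic), ],
                 n_obs = nrow(obs)),
            class = "modelfree_fit")
}

# pull per-residue R1/R2/nOe observation frames out of a rate table, in a
# canonical (residue, field, kind) order so results are independent of the
# input row order
.mf_observations <- function(table, state = "apo") {
  sel <- table[table$kind %in% c("R1", "R2", "nOe") & table$state == state, ]
  sel <- sel[order(sel$residue, sel$field, sel$kind), ]
  split(sel[, c("kind", "field", "value", "sigma")], sel$residue)
}

#' Fit the global diffusion model by alternating optimization
#'
#' Alternates (a) per-residue model-free fits with the diffusion fixed and
#' (b) re-optimization of the diffusion parameters with the per-residue
#' parameters fixed, until the summed chi^2 stabilizes. Supports isotropic
#' and axially symmetric tensors (an ellipsoid tensor is out of scope; the
#' axial case needs per-residue N-H unit vectors).
#'
#' @param table a [rate_table()] with R1/R2/nOe rows at one or two fields.
#' @param kind `"isotropic"` or `"axially_symmetric"`.
#' @param state "apo" or "bound".
#' @param window optional residue window restriction.
#' @param models per-residue model set used inside the alternation
#'   (default c("m1", "m2"): order parameter and internal time, no exchange,
#'   which keeps tau_c identifiable).
#' @param vectors named list (residue number -> length-3 N-H unit vector),
#'   required for the axial kind.
#' @param max_alt maximum alternations (default 20).
#' @param tol relative chi^2 convergence tolerance (default 1e-6).
#' @param constants [nmr_constants()].
#' @return list of class `diffusion_fit`: `diffusion` ([diffusion_model()]),
#'   `chisq`, `converged`, `n_residues`, `residue_fits`.
#' @export
fit_global_diffusion <- function(table, kind = "isotropic", state = "apo",
                                 window = NULL, models = c("m1", "m2"),
                                 vectors = NULL, max_alt = 20, tol = 1e-6,
                                 constants = nmr_constants()) {
  if (!is.null(window)) table <- filter_rates(table, window = window)
  obs_by_res <- .mf_observations(table, state = state)
  obs_by_res <- obs_by_res[vapply(obs_by_res, nrow, 0L) >= 3]
  if (length(obs_by_res) < 10)
    stop(sprintf("need >= 10 residues with >= 3 observables, got %d",
                 length(obs_by_res)))
  if (kind == "axially_symmetric" && is.null(vectors))
    stop("axially symmetric fit requires per-residue N-H unit vectors")
  fields <- sort(unique(table$field))
  tc0 <- tryCatch(
    estimate_tc_from_r2r1(table, window = range(as.integer(names(obs_by_res))),
                          field = fields[1], state = state,
                          constants = constants),
    error = function(e) 5e-9)
  vec_of <- function(res) if (is.null(vectors)) NULL else vectors[[res]]

  fit_residues <- function(diff) {
    lapply(names(obs_by_res), function(res)
      fit_modelfree_residue(obs_by_res[[res]], diff, models = models,
                            constants = constants, vec = vec_of(res)))
  }
  total_chisq <- function(diff, fits) {
    tot <- 0
    ctxs <- lapply(fields, spectrometer_context, constants = constants)
    names(ctxs) <- as.character(fields)
    for (i in seq_along(fits)) {
      res <- names(obs_by_res)[i]
      ob <- obs_by_res[[res]]
      sig <- ifelse(is.finite(ob$sigma) & ob$sigma > 0, ob$sigma,
                    pmax(abs(ob$value) * 0.02, 1e-6))
      for (r in seq_len(nrow(ob))) {
        pred <- predict_relaxation(fits[[i]]$params, diff,
                                   ctxs[[as.character(ob$field[r])]],
                                   constants, vec_of(res))
        p <- switch(ob$kind[r], R1 = pred$R1, R2 = pred$R2, nOe = pred$nOe)
        tot <- tot + ((ob$value[r] - p) / sig[r])^2
      }
    }
    tot
  }
  diff <- diffusion_model(kind, tc = tc0)
  fits <- fit_residues(diff)
  last <- total_chisq(diff, fits)
  converged <- FALSE
  for (it in seq_len(max_alt)) {
    if (kind == "isotropic") {
      op <- stats::optimize(function(tc)
        total_chisq(diffusion_model("isotropic", tc = tc), fits),
        interval = c(0.3 * diff$tc, 3 * diff$tc), tol = 1e-13)
      diff <- diffusion_model("isotropic", tc = op$minimum)
    } else {
      par0 <- c(log(diff$tc), log(diff$ratio), diff$theta, diff$phi)
      op <- stats::optim(par0, function(p)
        total_chisq(diffusion_model("axially_symmetric", tc = exp(p[1]),
                                    ratio = exp(p[2]), theta = p[3],
                                    phi = p[4]), fits),
        method = "Nelder-Mead", control = list(maxit = 400))
      diff <- diffusion_model("axially_symmetric", tc = exp(op$par[1]),
                              ratio = exp(op$par[2]), theta = op$par[3],
                              phi = op$par[4])
    }
    fits <- fit_residues(diff)
    cur <- total_chisq(diff, fits)
    if (abs(last - cur) <= tol * max(last, 1e-12)) { converged <- TRUE; break }
    last <- cur
  }
  if (!converged)
    warning(sprintf("diffusion fit not converged after %d alternations; returning last iterate (chi^2 = %g)",
                    max_alt, cur))
  names(fits) <- names(obs_by_res)
  structure(list(diffusion = diff, chisq = cur, converged = converged,
                 n_residues = length(fits), residue_fits = fits),
            class = "diffusion_fit")
}

#' Tabulate fitted Rex values with threshold flags
#'
#' @param fits named list of [fit_modelfree_residue()] results (names =
#'   residue numbers), e.g. the `residue_fits` of a [fit_global_diffusion()]
#'   result.
#' @param thresholds Rex flag thresholds, s^-1 (defaults 1 and 2).
#' @return data.frame: `residue`, `model`, `Rex`, one logical column per
#'   threshold (`rex_gt_1`, `rex_gt_2`, ...). Empty input gives an empty
#'   table.
#' @export
extract_rex_map <- function(fits, thresholds = c(1, 2)) {
  cols <- paste0("rex_gt_", sub("\\.", "_", as.character(thresholds)))
  if (!length(fits)) {
    out <- data.frame(residue = integer(0), model = character(0),
                      Rex = numeric(0))
    for (cl in cols) out[[cl]] <- logical(0)
    return(out)
  }
  out <- data.frame(
    residue = as.integer(names(fits)),
    model = vapply(fits, function(f) f$params$model_id, ""),
    Rex = vapply(fits, function(f) f$params$Rex, 0),
    row.names = NULL)
  for (i in seq_along(thresholds)) out[[cols[i]]] <- out$Rex > thresholds[i]
  out
}
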