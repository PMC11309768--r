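#' Default synthetic dsRBD-like ground truth
#'
#' An 80-residue synthetic protein patterned on the dsRBD2 construct: core
#' residues 159-227 (68 observed; one position, 170, is skipped the way a
#' proline lacks an amide) with rigid-core model-free parameters, flanked by
#' 12 flexible terminal/loop residues with low order parameters.
#'
#' @param S2_core core order parameter (default 0.85).
#' @param S2_term terminal order parameter (default 0.3).
#' @param te internal correlation time, s (default 50 ps).
#' @param tc global correlation time, s (default 7.3 ns, the apo value).
#' @return list: `residues` (integer vector), `params` (named list of
#'   [modelfree_params()]), `diffusion` ([diffusion_model()]).
#' @export
default_protein_truth <- function(S2_core = 0.85, S2_term = 0.3,
                                  te = 50e-12, tc = 7.3e-9) {
  residues <- setdiff(154:234, 170)
  params <- lapply(residues, function(r) {
    core <- is_core_residue(r)
    modelfree_params(S2 = if (core) S2_core else S2_term,
                     ts = te, model_id = "m2")
  })
  names(params) <- residues
  list(residues = residues, params = params,
       diffusion = diffusion_model("isotropic", tc = tc))
}

#' Generate mono-exponential decay datasets with known ground truth
#'
#' I(t) = I0 exp(-R t) + N(0, sigma I0); duplicate delays are independent
#' noise draws. The returned object embeds its ground truth, so any
#' downstream recovery test can be rerun from the sidecar alone.
#'
#' @param truth data.frame with columns `residue`, `rate` (s^-1) and
#'   optionally `I0` (default 100).
#' @param schedule a [delay_schedule()].
#' @param sigma relative noise (fraction of I0; >= 0).
#' @param seed RNG seed.
#' @return list of class `decay_dataset`: `series` (list of
#'   [intensity_series()]), `truth` (inputs + seed).
#' @export
gen_decay_dataset <- function(truth, schedule, sigma = 0.02, seed = NULL) {
  stopifnot(sigma >= 0)
  if (is.null(truth$I0)) truth$I0 <- 100
  ex <- expand_schedule(schedule)
  series <- with_seed(seed, {
    lapply(seq_len(nrow(truth)), function(i) {
      ideal <- truth$I0[i] * exp(-truth$rate[i] * ex$time)
      h <- ideal + if (sigma > 0)
        stats::rnorm(length(ideal), 0, sigma * truth$I0[i]) else 0
      intensity_series(residue_id(truth$residue[i]), schedule, h)
    })
  })
  names(series) <- truth$residue
  structure(list(series = series,
                 truth = list(rates = truth, schedule = schedule,
                              sigma = sigma, seed = seed)),
            class = "decay_dataset")
}

#' Generate a multi-field R1/R2/nOe rate table from model-free truth
#'
#' Forward-predicts R1, R2 and nOe at each field with
#' [predict_relaxation()] and adds relative Gaussian noise.
#'
#' @param params named list of [modelfree_params()] (names = residue
#'   numbers).
#' @param diffusion a [diffusion_model()].
#' @param fields proton frequencies, MHz (default c(600, 800)).
#' @param sigma relative noise fraction (default 0.02).
#' @param seed RNG seed; `state` row label; `constants` physics constants.
#' @param state "apo" or "bound" label for the generated rows.
#' @param constants an [nmr_constants()] object.
#' @return list of class `modelfree_dataset`: `table` ([rate_table()]),
#'   `truth`.
#' @export
gen_modelfree_dataset <- function(params, diffusion, fields = c(600, 800),
                                  sigma = 0.02, seed = NULL, state = "apo",
                                  constants = nmr_constants()) {
  stopifnot(length(fields) >= 1)
  rows <- list()
  for (f in fields) {
    ctx <- spectrometer_context(f, constants = constants)
    for (r in names(params)) {
      pred <- predict_relaxation(params[[r]], diffusion, ctx, constants)
      rows[[length(rows) + 1]] <- data.frame(
        residue = as.integer(r), kind = c("R1", "R2", "nOe"),
        value = c(pred$R1, pred$R2, pred$nOe),
        sigma = abs(c(pred$R1, pred$R2, pred$nOe)) * max(sigma, 1e-4),
        field = f, state = state, cond = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  if (sigma > 0)
    tab$value <- with_seed(seed,
      tab$value + stats::rnorm(nrow(tab), 0, abs(tab$value) * sigma))
  structure(list(table = rate_table(tab),
                 truth = list(params = params, diffusion = diffusion,
                              fields = fields, sigma = sigma, seed = seed)),
            class = "modelfree_dataset")
}

#' Generate a HARD dispersion dataset from two-state exchange truth
#'
#' Rotating-frame rates via [simulate_hard_rates()] plus relative Gaussian
#' noise, per residue.
#'
#' @param params named list of [exchange_params()] (names = residues).
#' @param pulses HSn pulse list (default [hs_pulse_set()]).
#' @param delays_r1rho,delays_r2rho delays, s (multiples of Tp).
#' @param sigma relative noise fraction (default 0.02).
#' @param seed RNG seed; `state` label.
#' @param state "apo" or "bound" label.
#' @return list of class `hard_dataset`: `rows` (named list of `hard_row`),
#'   `truth`.
#' @export
gen_hard_dataset <- function(params, pulses = hs_pulse_set(),
                             delays_r1rho = c(0, 16, 32, 64, 96, 128) / 1000,
                             delays_r2rho = c(0, 16, 32, 64) / 1000,
                             sigma = 0.02, seed = NULL, state = "apo") {
  clean <- lapply(params, simulate_hard_rates, pulses = pulses,
                  delays_r1rho = delays_r1rho, delays_r2rho = delays_r2rho)
  rows <- with_seed(seed, {
    lapply(clean, function(row) {
      if (sigma > 0) {
        row$R1rho <- row$R1rho * (1 + stats::rnorm(length(row$R1rho), 0, sigma))
        row$R2rho <- row$R2rho * (1 + stats::rnorm(length(row$R2rho), 0, sigma))
      }
      row
    })
  })
  structure(list(rows = rows, state = state,
                 truth = list(params = params, sigma = sigma, seed = seed,
                              delays_r1rho = delays_r1rho,
                              delays_r2rho = delays_r2rho)),
            class = "hard_dataset")
}

#' Generate a one-site titration curve with known truth
#'
#' Response from [titration_isotherm()] over an equivalents grid, plus
#' relative Gaussian noise (scaled by the saturating response). The zero
#' point (Lt = 0) always has a zero ideal response.
#'
#' @param model a [binding_model()] (Kd and ddmax used).
#' @param Pt total protein, M (default 50 uM).
#' @param equivalents increasing grid of \[L\]t/\[P\]t ratios.
#' @param sigma relative noise fraction of ddmax (default 0.02).
#' @param seed RNG seed.
#' @return list of class `titration_dataset`: `curve`
#'   ([titration_curve()]), `truth`.
#' @export
gen_titration_dataset <- function(model, Pt = 50e-6,
                                  equivalents = seq(0, 5, length.out = 12),
                                  sigma = 0.02, seed = NULL) {
  stopifnot(all(diff(equivalents) > 0))
  Lt <- equivalents * Pt
  ideal <- titration_isotherm(Pt, Lt, model$Kd, model$ddmax)
  y <- if (sigma > 0)
    with_seed(seed, ideal + stats::rnorm(length(ideal), 0,
                                         sigma * abs(model$ddmax)))
  else ideal
  structure(list(curve = titration_curve(Pt, Lt, y,
                                         sigma = sigma * abs(model$ddmax)),
                 truth = list(model = model, Pt = Pt,
                              equivalents = equivalents, sigma = sigma,
                              seed = seed)),
            class = "titration_dataset")
}

#' Generate a single-site ITC thermogram with known truth
#'
#' Wraps [simulate_itc()]; noise is specified as a fraction of the largest
#' ideal heat. The first (discardable) injection is honored.
#'
#' @param model a [binding_model()].
#' @param experiment an [itc_experiment()] geometry.
#' @param sigma relative noise fraction of the largest heat (default 0.02).
#' @param seed RNG seed.
#' @return list of class `itc_dataset`: `experiment` (heats filled),
#'   `truth`.
#' @export
gen_itc_dataset <- function(model, experiment, sigma = 0.02, seed = NULL) {
  ideal <- simulate_itc(model, experiment)
  abs_sigma <- sigma * max(abs(ideal$heats), 1e-12)
  out <- if (sigma > 0) simulate_itc(model, experiment, sigma = abs_sigma,
                                     seed = seed)
         else ideal
  structure(list(experiment = out,
                 truth = list(model = model, sigma = sigma, seed = seed)),
            class = "itc_dataset")
}

#' RNA duplex (two strands, both written 5' to 3')
#' @param guide,passenger RNA sequences over A/C/G/U.
#' @return object of class `rna_duplex`.
#' @export
rna_duplex <- function(guide, passenger) {
  chk <- function(s, what) {
    s <- toupper(gsub("[[:space:]]", "", s))
    if (!nzchar(s)) stop(what, " strand is empty")
    if (grepl("[^ACGU]", s))
      stop(what, " strand contains non-ACGU characters")
    s
  }
  structure(list(guide = chk(guide, "guide"),
                 passenger = chk(passenger, "passenger")),
            class = "rna_duplex")
}

#' Count base pairs of an antiparallel RNA duplex
#'
#' Guide position i pairs with passenger position L + 1 - i. Watson-Crick
#' pairs are AU/UA/GC/CG; G.U/U.G wobbles count when `allow_wobble`. For
#' strands of unequal length every ungapped antiparallel register is tried
#' and the one pairing the most positions is used (ties broken toward the
#' centred register); overhanging bases are reported.
#'
#' @param duplex an [rna_duplex()].
#' @param allow_wobble count G.U wobbles as paired (default TRUE).
#' @return list: `wc`, `wobble`, `total_paired`, `overhang`.
#' @export
count_base_pairs <- function(duplex, allow_wobble = TRUE) {
  g <- strsplit(duplex$guide, "")[[1]]
  r <- rev(strsplit(duplex$passenger, "")[[1]]) # antiparallel partner
  n1 <- length(g); n2 <- length(r)
  wc_set <- c("AU", "UA", "GC", "CG")
  wob_set <- c("GU", "UG")
  score <- function(s) {
    i <- seq_len(n1)
    j <- i + s
    ok <- j >= 1 & j <= n2
    pr <- paste0(g[i[ok]], r[j[ok]])
    wc <- sum(pr %in% wc_set)
    wob <- sum(pr %in% wob_set)
    list(wc = wc, wobble = if (allow_wobble) wob else 0L,
         total = wc + if (allow_wobble) wob else 0L)
  }
  shifts <- seq(-(n1 - 1), n2 - 1)
  shifts <- shifts[order(abs(shifts - (n2 - n1) / 2))] # centred first
  best <- NULL; best_s <- 0
  for (s in shifts) {
    sc <- score(s)
    if (is.null(best) || sc$total > best$total) { best <- sc; best_s <- s }
  }
  list(wc = best$wc, wobble = best$wobble, total_paired = best$total,
       overhang = (n1 - best$total) + (n2 - best$total),
       shift = best_s)
}
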