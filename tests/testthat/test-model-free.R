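test_that("spectral density has the rigid-limit value and nests correctly", {
  dif <- diffusion_model("isotropic", tc = 7.3e-9)
  rigid <- modelfree_params(S2 = 1)
  expect_equal(spectral_density(rigid, dif, 0), 2 * 7.3e-9 / 5,
               tolerance = 1e-12)
  # Sf2 = 1 reduces the extended form to the original Lipari-Szabo form
  w <- 10^seq(6, 10, length.out = 25)
  ext <- modelfree_params(S2 = 0.8, Sf2 = 1, ts = 200e-12)
  # original form computed directly
  tsp <- 1 / (1 / 7.3e-9 + 1 / 200e-12)
  orig <- 0.4 * (0.8 * 7.3e-9 / (1 + (w * 7.3e-9)^2) +
                 0.2 * tsp / (1 + (w * tsp)^2))
  expect_equal(spectral_density(ext, dif, w), orig, tolerance = 1e-12)
})

test_that("J(omega) is non-negative, non-increasing, and matches quadrature", {
  dif <- diffusion_model("isotropic", tc = 7.3e-9)
  set.seed(17)
  for (i in 1:5) {
    sf2 <- runif(1, 0.6, 1)
    p <- modelfree_params(S2 = runif(1, 0.2, sf2), Sf2 = sf2,
                          tf = runif(1, 0, 30e-12), ts = runif(1, 0, 2e-9))
    w <- 10^seq(5, 10.5, length.out = 40)
    J <- spectral_density(p, dif, w)
    expect_true(all(J >= 0))
    expect_true(all(diff(J) <= 1e-15))
    # quadrature oracle: J(w) = 2 * integral of C(t) cos(wt) dt, with C(t)
    # the tri-exponential correlation function the model implies
    Cfun <- function(t) {
      tc <- 7.3e-9
      tfp <- if (p$tf > 0) 1 / (1 / tc + 1 / p$tf) else NA
      tsp <- if (p$ts > 0) 1 / (1 / tc + 1 / p$ts) else NA
      v <- p$S2 * exp(-t / tc)
      if (p$tf > 0) v <- v + (1 - p$Sf2) * exp(-t / tfp)
      if (p$ts > 0) v <- v + (p$Sf2 - p$S2) * exp(-t / tsp)
      v / 5
    }
    for (wi in c(0, abs(spectrometer_context(600)$omegaN))) {
      q <- stats::integrate(function(t) 2 * Cfun(t) * cos(wi * t),
                            0, 60 * 7.3e-9, rel.tol = 1e-9,
                            subdivisions = 2000L)$value
      expect_equal(spectral_density(p, dif, wi), q, tolerance = 1e-4)
    }
  }
})

test_that("predicted relaxation obeys known limits and additivity", {
  dif <- diffusion_model("isotropic", tc = 7.3e-9)
  # slow-tumbling side: rigid R1 lower at the higher field
  rigid <- modelfree_params(S2 = 1)
  r600 <- predict_relaxation(rigid, dif, spectrometer_context(600))
  r800 <- predict_relaxation(rigid, dif, spectrometer_context(800))
  expect_gt(r600$R1, r800$R1)
  expect_gt(r600$R1, 0); expect_gt(r600$R2, 0)
  # extreme narrowing with pure dipolar relaxation: nOe -> 1 + gH/(2 gN)
  k0 <- nmr_constants(dsigmaN = 0)
  pn <- predict_relaxation(modelfree_params(S2 = 1),
                           diffusion_model("isotropic", tc = 1e-12),
                           spectrometer_context(600, constants = k0), k0)
  expect_equal(pn$nOe, 1 + k0$gammaH / (2 * k0$gammaN), tolerance = 1e-3)
  # Rex adds exactly to R2 at the reference field, nothing to R1/nOe
  base <- modelfree_params(S2 = 0.85, ts = 50e-12)
  wrex <- modelfree_params(S2 = 0.85, ts = 50e-12, Rex = 2)
  p0 <- predict_relaxation(base, dif, spectrometer_context(600))
  p2 <- predict_relaxation(wrex, dif, spectrometer_context(600))
  expect_equal(p2$R2 - p0$R2, 2, tolerance = 1e-12)
  expect_equal(p2$R1, p0$R1)
  expect_equal(p2$nOe, p0$nOe)
  # quadratic field scaling of Rex
  p8 <- predict_relaxation(wrex, dif, spectrometer_context(800))
  b8 <- predict_relaxation(base, dif, spectrometer_context(800))
  expect_equal(p8$R2 - b8$R2, 2 * (800 / 600)^2, tolerance = 1e-12)
})

test_that("tau_c estimation from R2/R1 round-trips the forward model", {
  # rigid synthetic data at 7.3 ns recover within 2%
  truth <- lapply(1:10, function(i) modelfree_params(S2 = 1))
  names(truth) <- 159 + seq_len(10)
  dif <- diffusion_model("isotropic", tc = 7.3e-9)
  tab <- gen_modelfree_dataset(truth, dif, fields = 600, sigma = 0)$table
  tc <- estimate_tc_from_r2r1(tab, c(159, 227))
  expect_equal(tc, 7.3e-9, tolerance = 0.02)
  # ratio -> tc inversion is the exact inverse of prediction over [2, 15] ns
  for (tcv in c(2e-9, 5e-9, 10e-9, 15e-9)) {
    p <- predict_relaxation(modelfree_params(S2 = 1),
                            diffusion_model("isotropic", tc = tcv),
                            spectrometer_context(600))
    expect_equal(spindyn:::ratio_tc(p$R2 / p$R1, 600), tcv, tolerance = 1e-3)
  }
  # monotonicity: scaling R2 up increases the estimate
  tab2 <- tab
  tab2$value[tab2$kind == "R2"] <- tab2$value[tab2$kind == "R2"] * 1.2
  expect_gt(estimate_tc_from_r2r1(rate_table(as.data.frame(tab2)),
                                  c(159, 227)), tc)
  # too few rigid candidates -> error
  tab3 <- tab
  tab3$value[tab3$kind == "nOe"] <- 0.2
  expect_error(estimate_tc_from_r2r1(rate_table(as.data.frame(tab3)),
                                     c(159, 227)), "rigid-candidate")
})

test_that("per-residue model selection recovers generating models", {
  dif <- diffusion_model("isotropic", tc = 7.3e-9)
  # noiseless rigid data -> m0/m1 with S2 >= 0.99
  f0 <- fit_modelfree_residue(mf_obs(modelfree_params(S2 = 1), dif), dif)
  expect_true(f0$params$model_id %in% c("m0", "m1"))
  expect_gte(f0$params$S2, 0.99)
  # Rex-bearing data select an Rex model with Rex in [1.5, 4.5]
  frex <- fit_modelfree_residue(
    mf_obs(modelfree_params(S2 = 0.85, ts = 50e-12, Rex = 3), dif,
           sigma = 0.02, seed = 5), dif)
  expect_true(frex$params$model_id %in% c("m3", "m4", "m7", "m8"))
  expect_gte(frex$params$Rex, 1.5)
  expect_lte(frex$params$Rex, 4.5)
  # selection never prefers a super-model on noiseless nested data
  f2 <- fit_modelfree_residue(
    mf_obs(modelfree_params(S2 = 0.85, ts = 50e-12), dif), dif)
  expect_true(f2$params$model_id %in% c("m1", "m2"))
  expect_error(fit_modelfree_residue(
    mf_obs(modelfree_params(S2 = 1), dif)[1:2, ], dif), "nrow")
})

test_that("m2 recovery holds over 50 seeded replicates at 2% two-field noise", {
  dif <- diffusion_model("isotropic", tc = 7.3e-9)
  truth <- modelfree_params(S2 = 0.85, ts = 50e-12)
  sel <- 0; s2ok <- 0
  for (i in 1:50) {
    f <- fit_modelfree_residue(mf_obs(truth, dif, sigma = 0.02, seed = i), dif)
    if (f$params$model_id == "m2") sel <- sel + 1
    if (abs(f$params$S2 - 0.85) <= 0.05) s2ok <- s2ok + 1
  }
  expect_gte(sel, 45)   # >= 90%
  expect_gte(s2ok, 45)
})

test_that("global isotropic diffusion fit recovers tau_c and ignores residue order", {
  pars <- lapply(1:12, function(i) modelfree_params(S2 = 0.85, ts = 50e-12))
  names(pars) <- 159 + seq_len(12)
  dif <- diffusion_model("isotropic", tc = 10.9e-9) # bound-state value
  ds <- gen_modelfree_dataset(pars, dif, sigma = 0.02, seed = 21)
  fit <- fit_global_diffusion(ds$table)
  expect_equal(fit$diffusion$tc, 10.9e-9, tolerance = 0.03)
  expect_true(fit$converged)
  # permutation invariance of the residue set
  tab2 <- ds$table[sample(nrow(ds$table)), ]
  fit2 <- fit_global_diffusion(rate_table(as.data.frame(tab2)))
  expect_equal(fit2$diffusion$tc, fit$diffusion$tc, tolerance = 1e-12)
  # bound-state tc exceeds apo tc when generated so
  ds_apo <- gen_modelfree_dataset(pars, diffusion_model("isotropic", tc = 7.3e-9),
                                  sigma = 0.02, seed = 22)
  fit_apo <- fit_global_diffusion(ds_apo$table)
  expect_gt(fit$diffusion$tc, fit_apo$diffusion$tc)
  expect_error(fit_global_diffusion(filter_rates(ds$table, window = c(159, 163))),
               ">= 10 residues")
})

test_that("axial diffusion with ratio 1 reduces to the isotropic answer", {
  pars <- lapply(1:10, function(i) modelfree_params(S2 = 0.9))
  names(pars) <- 200 + seq_len(10)
  vecs <- lapply(1:10, function(i) {
    v <- c(sin(i), cos(i), sin(2 * i + 1)); v / sqrt(sum(v^2))
  })
  names(vecs) <- names(pars)
  dif <- diffusion_model("isotropic", tc = 7.3e-9)
  ds <- gen_modelfree_dataset(pars, dif, sigma = 0, seed = 1)
  fax <- fit_global_diffusion(ds$table, kind = "axially_symmetric",
                              vectors = vecs, models = "m1", max_alt = 4)
  expect_equal(fax$diffusion$tc, 7.3e-9, tolerance = 0.01)
  expect_error(fit_global_diffusion(ds$table, kind = "axially_symmetric"),
               "unit vectors")
})

test_that("Rex maps flag thresholds monotonically", {
  mk <- function(rex) list(params = modelfree_params(S2 = 0.85, Rex = rex,
                                                     model_id = "m3"))
  fits <- list(`160` = mk(0), `161` = mk(1.5), `162` = mk(3))
  tab <- extract_rex_map(fits)
  expect_equal(tab$rex_gt_1, c(FALSE, TRUE, TRUE))
  expect_equal(tab$rex_gt_2, c(FALSE, FALSE, TRUE))
  # flagged-at-2 is a subset of flagged-at-1
  expect_true(all(tab$residue[tab$rex_gt_2] %in% tab$residue[tab$rex_gt_1]))
  empty <- extract_rex_map(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("rex_gt_1", "rex_gt_2") %in% names(empty)))
})
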