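test_that("HSn pulses satisfy the waveform invariants", {
  for (n in c(1, 2, 4, 8)) {
    p <- build_hs_pulse(n, npoints = 256)
    # analytic endpoint symmetry and peak amplitude
    expect_equal(pulse_amplitude(p, 0), pulse_amplitude(p, p$Tp),
                 tolerance = 1e-9)
    expect_equal(pulse_amplitude(p, p$Tp / 2), p$w1max, tolerance = 1e-12)
    # sampled waveform is symmetric about Tp/2
    expect_equal(p$amp, rev(p$amp), tolerance = 1e-9)
    # offset sweeps the band monotonically
    expect_lt(abs(p$offset[1] + p$bandwidth / 2) / p$bandwidth, 0.01)
    expect_lt(abs(p$offset[p$npoints] - p$bandwidth / 2) / p$bandwidth, 0.01)
    expect_true(all(diff(p$offset) > 0))
  }
  # higher stretching factor -> flatter profile -> larger mean amplitude
  means <- vapply(c(1, 2, 4, 6, 8),
                  function(n) mean(build_hs_pulse(n, npoints = 256)$amp),
                  numeric(1))
  expect_true(all(diff(means) > 0))
  expect_error(build_hs_pulse(0), "integer")
  expect_error(build_hs_pulse(1, npoints = 32), "64")
})

test_that("BM propagation is an isometry without relaxation and exchange-balanced", {
  m <- exchange_params(pB = 0.2, kex = 0, domega = 0, R1g = 0, R2g = 0)
  expect_equal(m$pA + m$pB, 1)
  expect_equal(m$kab + m$kba, m$kex)
  p <- build_hs_pulse(4, npoints = 256)
  tr <- bm_propagate(m, p, M0 = c(0, 0, 1), n_pulses = 8) # 128 ms
  Mtot <- tr[, 1:3] + tr[, 4:6]
  expect_lt(max(abs(sqrt(rowSums(Mtot^2)) - 1)), 1e-8)
  # with relaxation on, total magnetization never grows
  m2 <- exchange_params(pB = 0.1, kex = 2000, domega = 500, R1g = 1.5,
                        R2g = 11)
  tr2 <- bm_propagate(m2, p, M0 = c(0, 0, 1), n_pulses = 8)
  norms <- sqrt(rowSums((tr2[, 1:3] + tr2[, 4:6])^2))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("constant-lock decay matches R1 cos^2 + R2 sin^2 in the pB->0 limit", {
  for (th_deg in c(20, 45, 70)) {
    th <- th_deg * pi / 180
    w1 <- 2 * pi * 1500
    lock <- constant_lock_pulse(w1, w1 / tan(th), Tp = 0.004, npoints = 64)
    m <- exchange_params(pB = 1e-6, kex = 0, domega = 0, R1g = 1.5, R2g = 11)
    ax <- c(sin(th), 0, cos(th))
    tr <- bm_propagate(m, lock, M0 = ax, n_pulses = 10)
    sig <- vapply(0:10, function(k)
      sum((tr[k + 1, 1:3] + tr[k + 1, 4:6]) * ax), numeric(1))
    rate <- -stats::coef(stats::lm(log(sig) ~ I((0:10) * lock$Tp)))[[2]]
    closed <- 1.5 * cos(th)^2 + 11 * sin(th)^2
    expect_equal(rate, closed, tolerance = 0.01)
  }
})

test_that("Laguerre-style two-state R1rho holds for constant on-resonance locks", {
  # asymptotic (Trott-Palmer) oracle: on-resonance lock at angle 90 deg,
  # R1rho = R2 + Rex with Rex = pA pB dw^2 kex / (kex^2 + w1^2), valid for
  # skewed populations outside slow exchange
  for (cfg in list(c(2000, 0.05), c(10000, 0.1), c(50000, 0.2))) {
    kex <- cfg[1]; pB <- cfg[2]
    dw <- 2 * ppm2rad(600)
    w1 <- 2 * pi * 800
    m <- exchange_params(pB = pB, kex = kex, domega = dw, R1g = 1.5, R2g = 11)
    lock <- constant_lock_pulse(w1, 0, Tp = 0.002, npoints = 64)
    ax <- c(1, 0, 0)
    tr <- bm_propagate(m, lock, M0 = ax, n_pulses = 16)
    sig <- vapply(0:16, function(k)
      sum((tr[k + 1, 1:3] + tr[k + 1, 4:6]) * ax), numeric(1))
    rate <- -stats::coef(stats::lm(log(sig) ~ I((0:16) * lock$Tp)))[[2]]
    rex <- pB * (1 - pB) * dw^2 * kex / (kex^2 + w1^2)
    expect_equal(rate, 11 + rex, tolerance = 0.05)
  }
})

test_that("step-halving convergence holds at default resolution and is enforced", {
  m <- exchange_params(pB = 0.1, kex = 3000, domega = 2 * ppm2rad(600),
                       R1g = 1.5, R2g = 11)
  p <- build_hs_pulse(4) # default npoints = 1024
  tr <- bm_propagate(m, p, n_pulses = 2, check_step = TRUE)
  expect_equal(nrow(tr), 3)
  # a deliberately coarse waveform fails the doubling test
  coarse <- build_hs_pulse(4, npoints = 64)
  expect_error(
    bm_propagate(m, coarse, n_pulses = 2, check_step = TRUE, step_tol = 1e-9),
    "step-doubling")
})

test_that("HARD rates show the tilt baseline without exchange and extra dispersion with it", {
  pulses <- test_pulses(ns = c(1, 2, 4, 6, 8))
  none <- exchange_params(pB = 0.05, kex = 0, domega = 0, R1g = 1.5, R2g = 11)
  r0 <- simulate_hard_rates(none, pulses)
  # the paper's qualitative signature: R1rho rises, R2rho falls with n,
  # already present without exchange (tilt-angle trajectory effect)
  expect_true(all(diff(r0$R1rho) > 0))
  expect_true(all(diff(r0$R2rho) < 0))
  # rates bounded by the intrinsic pair
  expect_true(all(r0$R1rho > 1.5 & r0$R1rho < 11))
  # exchange leaves R1rho nearly unchanged but inflates R2rho dispersion
  ex <- exchange_params(pB = 0.1, kex = 3000, domega = 2 * ppm2rad(600),
                        R1g = 1.5, R2g = 11)
  r1 <- simulate_hard_rates(ex, pulses)
  expect_true(all(diff(r1$R1rho) > 0))
  expect_true(all(diff(r1$R2rho) < 0))
  expect_gt(diff(range(r1$R2rho)), 2 * diff(range(r0$R2rho)))
  expect_gt(min(r1$R2rho), max(r0$R2rho)) # exchange broadens throughout
  # invisible exchange: domega = 0 is identical to no exchange
  dw0 <- exchange_params(pB = 0.1, kex = 20000, domega = 0, R1g = 1.5,
                         R2g = 11)
  r2 <- simulate_hard_rates(dw0, pulses)
  expect_equal(r2$R1rho, r0$R1rho, tolerance = 1e-8)
  expect_equal(r2$R2rho, r0$R2rho, tolerance = 1e-8)
  # delays must be multiples of Tp
  expect_error(simulate_hard_rates(ex, pulses, delays_r1rho = c(0, 0.01)),
               "integer multiples")
})

test_that("two-state fitting recovers (pB, kex) and returns sentinels on flat data", {
  pulses <- test_pulses()
  grid_small <- list(kex = c(2, 6, 10), pB = c(0.01, 0.5, 8),
                     dw_ppm = c(0.2, 6, 6))
  truth <- exchange_params(pB = 0.15, kex = 8000, domega = 2 * ppm2rad(600),
                           R1g = 1.5, R2g = 11)
  clean <- simulate_hard_rates(truth, pulses)
  ok <- 0
  for (i in 1:10) {
    set.seed(1000 + i)
    row <- clean
    row$R1rho <- row$R1rho * (1 + rnorm(3, 0, 0.02))
    row$R2rho <- row$R2rho * (1 + rnorm(3, 0, 0.02))
    f <- fit_two_state(row, pulses, mc_n = 0, fix_dw = 2, fix_r2g = 11,
                       grid = grid_small)
    if (!f$no_exchange && f$kex / 8000 < 1.5 && f$kex / 8000 > 1 / 1.5 &&
        abs(f$pB - 0.15) <= 0.05) ok <- ok + 1
  }
  expect_gte(ok, 8) # >= 80% of replicates
  # noisy exchange-free data -> sentinel via the baseline model
  none <- exchange_params(pB = 0.05, kex = 0, domega = 0, R1g = 1.5, R2g = 11)
  r0 <- simulate_hard_rates(none, pulses)
  set.seed(4)
  r0$R1rho <- r0$R1rho * (1 + rnorm(3, 0, 0.02))
  r0$R2rho <- r0$R2rho * (1 + rnorm(3, 0, 0.02))
  f0 <- fit_two_state(r0, pulses, mc_n = 0, grid = grid_small)
  expect_true(f0$no_exchange)
  # literally flat data -> sentinel via the raw-flatness shortcut
  flat <- list(R1 = 1.5, R1rho = rep(8, 3), R2rho = rep(8, 3))
  names(flat$R1rho) <- names(flat$R2rho) <- names(pulses)
  f1 <- fit_two_state(flat, pulses, sigma = 0.3, mc_n = 0, grid = grid_small)
  expect_true(f1$no_exchange)
})

test_that("Monte-Carlo errors of the two-state fit are seeded and reproducible", {
  pulses <- test_pulses()
  grid_small <- list(kex = c(2, 6, 6), pB = c(0.01, 0.5, 5),
                     dw_ppm = c(0.2, 6, 4))
  truth <- exchange_params(pB = 0.15, kex = 8000, domega = 2 * ppm2rad(600),
                           R1g = 1.5, R2g = 11)
  row <- simulate_hard_rates(truth, pulses)
  set.seed(2)
  row$R1rho <- row$R1rho * (1 + rnorm(3, 0, 0.02))
  row$R2rho <- row$R2rho * (1 + rnorm(3, 0, 0.02))
  f1 <- fit_two_state(row, pulses, mc_n = 10, seed = 7, fix_dw = 2,
                      fix_r2g = 11, grid = grid_small)
  f2 <- fit_two_state(row, pulses, mc_n = 10, seed = 7, fix_dw = 2,
                      fix_r2g = 11, grid = grid_small)
  expect_identical(f1, f2)
  expect_true(is.finite(f1$kex_sigma) && f1$kex_sigma > 0)
  expect_true(is.finite(f1$pB_sigma))
})

test_that("exchange classification bins follow the published thresholds", {
  mk <- function(kex, pB) structure(list(no_exchange = FALSE, kex = kex,
                                         pB = pB), class = "exchange_fit")
  expect_equal(classify_exchange(mk(60000, 0.15))$kex_class, "very_fast")
  expect_equal(classify_exchange(mk(4999, 0.05))$kex_class, "slow")
  expect_equal(classify_exchange(mk(5000, 0.05))$kex_class, "fast")
  expect_equal(classify_exchange(mk(50000, 0.05))$kex_class, "fast")
  expect_equal(classify_exchange(mk(60000, 0.15))$pb_class, "10-20%")
  expect_equal(classify_exchange(mk(100, 0.45))$pb_class, ">40%")
  sentinel <- structure(list(no_exchange = TRUE), class = "exchange_fit")
  expect_equal(classify_exchange(sentinel)$kex_class, "none")
})

test_that("very fast exchange classifies stably across seeds", {
  pulses <- test_pulses()
  grid_small <- list(kex = c(2, 6, 10), pB = c(0.01, 0.5, 8),
                     dw_ppm = c(0.2, 6, 6))
  truth <- exchange_params(pB = 0.2, kex = 80000, domega = 3 * ppm2rad(600),
                           R1g = 1.5, R2g = 11)
  clean <- simulate_hard_rates(truth, pulses)
  # far above the attainable spin-lock field only pB(1-pB)/kex is data-
  # constrained, so the robustness study conditions on the generating pB
  # (and dw, R2g) and asks whether the recovered kex bin is stable
  classes <- character(10)
  for (i in 1:10) {
    set.seed(2000 + i)
    row <- clean
    row$R1rho <- row$R1rho * (1 + rnorm(3, 0, 0.02))
    row$R2rho <- row$R2rho * (1 + rnorm(3, 0, 0.02))
    f <- fit_two_state(row, pulses, mc_n = 0, fix_dw = 3, fix_pb = 0.2,
                       fix_r2g = 11, grid = grid_small)
    classes[i] <- classify_exchange(f)$kex_class
  }
  expect_gte(sum(classes == "very_fast"), 8)
})

test_that("delta kex tables flag induced and quenched exchange at 10,000 s^-1", {
  mk <- function(kex) structure(list(no_exchange = FALSE, kex = kex, pB = 0.1),
                                class = "exchange_fit")
  apo <- list(`200` = mk(3000), `212` = mk(20000), `224` = mk(10000))
  bound <- list(`200` = mk(20000), `212` = mk(3000), `224` = mk(19999))
  tab <- delta_kex(apo, bound)
  expect_equal(tab$delta_kex, c(17000, -17000, 9999))
  expect_equal(tab$flagged, c(TRUE, TRUE, FALSE)) # |9,999| is unflagged
  expect_equal(tab$direction[1:2], c("induced", "quenched"))
  # missing-state marker
  tab2 <- delta_kex(apo["200"], bound)
  expect_equal(tab2$missing_state[tab2$residue != 200], c("apo", "apo"))
  expect_true(all(is.na(tab2$delta_kex[tab2$residue != 200])))
})
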