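# shared fixtures, built in code

# the inversion-recovery schedule (ms, * = duplicate)
r1_schedule <- function() {
  read_delay_schedule("10, 30*, 50, 100, 200, 300, 450*, 600")
}

# CPMG frequency list (Hz) as printed for the dispersion experiment
nu_cpmg_list <- function() c(25, 50, 75, 125, 175, 275, 375, 525, 675, 825, 1000)

# noiseless exponential series at the R1 schedule
exp_series <- function(rate, I0 = 100, residue = 160, schedule = r1_schedule()) {
  ex <- expand_schedule(schedule)
  intensity_series(residue_id(residue), schedule, I0 * exp(-rate * ex$time))
}

# per-residue observation frame from model-free truth, relative noise
mf_obs <- function(params, diffusion, fields = c(600, 800), sigma = 0,
                   seed = NULL) {
  rows <- list()
  vals <- c()
  for (f in fields) {
    p <- predict_relaxation(params, diffusion, spectrometer_context(f))
    rows[[length(rows) + 1]] <- data.frame(
      kind = c("R1", "R2", "nOe"), field = f,
      value = c(p$R1, p$R2, p$nOe),
      sigma = abs(c(p$R1, p$R2, p$nOe)) * max(sigma, 1e-4))
  }
  obs <- do.call(rbind, rows)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs$value <- obs$value * (1 + stats::rnorm(nrow(obs), 0, sigma))
  }
  obs
}

# small, fast HSn pulse set for fitting tests
test_pulses <- function(ns = c(1, 4, 8), npoints = 96) {
  hs_pulse_set(ns = ns, npoints = npoints)
}

# 15N rad/s per ppm at a given proton field
ppm2rad <- function(field = 600) abs(spectrometer_context(field)$omegaN) * 1e-6

# independent brute-force oracle for the mono-exponential fit: dense grid
# over R with the amplitude profiled in closed form
grid_monoexp_oracle <- function(t, y, r_range = c(0.05, 5), dr = 0.002) {
  rs <- seq(r_range[1], r_range[2], by = dr)
  rss <- vapply(rs, function(R) {
    e <- exp(-R * t)
    I0 <- sum(y * e) / sum(e^2)
    sum((y - I0 * e)^2)
  }, numeric(1))
  rs[which.min(rss)]
}
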