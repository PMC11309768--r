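# Builds inst/extdata/synthetic_core_rates.csv: a SYNTHETIC stand-in for a
# per-residue relaxation summary table of a dsRBD2-like domain. The real
# per-residue tables live in an external data deposition; this stand-in is
# constructed so that its core-window (159-227) summary statistics equal the
# published core averages (R1 1.43 s^-1, R2 apo 10.92 s^-1, R2 bound
# 20.04 s^-1, nOe 0.73 at 600 MHz), with deterministic per-residue scatter
# of realistic width. It exists to exercise the read -> filter -> aggregate
# path, not to reproduce any residue-level measurement.
# Run from the package root: Rscript tools/make_extdata.R

suppressMessages(library(spindyn))

core <- setdiff(159:227, 170)    # 68 observed core residues (one Pro)
flank <- c(154:158, 228:234)

set.seed(20260928)
mk <- function(res, mean_val, sd_val, kind, state, flank_scale = 0.7) {
  v <- rnorm(length(res), 0, sd_val)
  v <- v - mean(v[res %in% core])            # recentre core exactly
  val <- mean_val + v
  val[!(res %in% core)] <- val[!(res %in% core)] * flank_scale
  data.frame(residue = res, kind = kind, value = val,
             sigma = abs(val) * 0.03, field = 600, state = state,
             cond = NA_character_)
}
res <- c(flank, core)
res <- sort(res)
tab <- rbind(
  mk(res, 1.43, 0.20, "R1", "apo", flank_scale = 1.0),
  mk(res, 10.92, 1.50, "R2", "apo"),
  mk(res, 0.73, 0.08, "nOe", "apo"),
  mk(res, 20.04, 2.00, "R2", "bound")
)
tab <- rate_table(tab)
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_rate_table(tab, "inst/extdata/synthetic_core_rates.csv")
cat("wrote", nrow(tab), "rows\n")
for (k in list(c("R1", "apo"), c("R2", "apo"), c("nOe", "apo"), c("R2", "bound"))) {
  st <- aggregate_region_stats(tab, c(159, 227), k[1], 600, k[2])
  cat(sprintf("%s %s: mean %.4f sem %.4f n %d\n", k[1], k[2], st$mean, st$sem, st$n))
}
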