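# spindyn

Backbone amide ^15^N spin-relaxation dynamics and protein–RNA binding
analysis for double-stranded RNA-binding domains (dsRBDs), with a
ground-truth synthetic-data generator for end-to-end validation.

The package is aimed at protein NMR practitioners who have per-residue peak
heights (not spectra) in hand and want, in one place:

* **Relaxation rates** — mono-exponential R1/R2/R1ρ/R2ρ fits of peak height
  versus delay, duplicate-delay noise estimation
  σ = √(Σdᵢ²/2m), Monte-Carlo rate uncertainties (n = 500, seeded), the
  steady-state [¹H]-¹⁵N nOe with RMSD-propagated errors, constant-time CPMG
  R2,eff = −ln(I_ν/I_ref)/T_relax with an F-test dispersion call, and
  core-window mean ± SEM summaries.
* **Model-free analysis** — the extended Lipari–Szabo spectral density
  J(ω) = (2/5)[S²τc/(1+(ωτc)²) + (Sf²−S²)τ′/(1+(ωτ′)²) + …], standard
  dipolar+CSA forward prediction of (R1, R2, nOe) at multiple fields, the
  m0–m8 model ladder with small-sample AICc selection, τc initialization
  from R2/R1 and a global isotropic or axially symmetric diffusion fit by
  alternating optimization, and Rex maps flagged at 1 and 2 s⁻¹.
* **Adiabatic relaxation dispersion (HARD)** — hyperbolic-secant HSn
  spin-lock pulse construction, direct 6×6 two-state Bloch–McConnell
  propagation (compiled matrix exponentials), simulation of R1ρ/R2ρ across
  HS1…HS8, two-state (pB, kex, Δω, R2g) fitting with grid + local
  refinement and seeded Monte-Carlo errors, exchange classification at the
  5,000/50,000 s⁻¹ and 10/20/40% pB bins, and apo-vs-bound Δkex tables
  flagged above 10,000 s⁻¹.
* **Binding** — the quadratic two-state complex solver, the one-site NMR
  titration isotherm Δδobs = Δδmax(Pt+Lt+Kd − √((Pt+Lt+Kd)²−4PtLt))/(2Pt),
  combined CSP = √(ΔδH² + (0.14 ΔδN)²), and single-site ITC simulation and
  fitting (Wiseman isotherm with displaced-volume correction, discarded
  first injection, dilution offset, ΔG/ΔS derivation).
* **Synthetic data** — seeded generators for every stage above with the
  ground truth embedded, plus an RNA-duplex Watson–Crick / G·U wobble
  pairing counter.

## Worked example

Simulate a dsRBD2-like ITC titration (10 µM RNA duplex in a 200 µl cell,
130 µM protein in the syringe, one discarded 0.4 µl plus eighteen 2 µl
injections) and refit it:

```r
library(spindyn)

truth <- binding_model(Kd = 1.18e-6, dH = -10.12, n = 1)   # M, kcal/mol
geom  <- itc_experiment(V0 = 200e-6, cell_conc = 10e-6, syringe_conc = 130e-6)
d     <- gen_itc_dataset(truth, geom, sigma = 0.02, seed = 101)
fit   <- fit_itc_single_site(d$experiment, mc_n = 100, seed = 1)
cat(sprintf("Kd = %.2f uM, dH = %.2f kcal/mol, n = %.2f, dS = %+.4f kcal/mol/K\n",
            fit$Kd * 1e6, fit$dH, fit$n, fit$dS))
#> Kd = 1.20 uM, dH = -10.12 kcal/mol, n = 0.97, dS = -0.0069 kcal/mol/K
```

The fitted dissociation constant and enthalpy recover the generating values
within the 2% heat noise (the micromolar Kd and the negative entropy mark
an enthalpy-driven binder), and the quadratic solver confirms why amide
line broadening at 0.1 RNA equivalents cannot come from a saturated
complex:

```r
fb <- solve_fraction_bound(Pt = 50e-6, Lt = 5e-6, Kd = 1.7e-6)
round(100 * fb$fraction_P, 1)   # percent protein bound
#> 9.6
```

A two-field relaxation dataset generated from rigid-core model-free truth
refits the global correlation time:

```r
pars <- setNames(lapply(1:60, function(i) modelfree_params(S2 = 0.85, ts = 50e-12)),
                 158 + 1:60)
ds  <- gen_modelfree_dataset(pars, diffusion_model("isotropic", tc = 7.3e-9),
                             fields = c(600, 800), sigma = 0.02, seed = 11)
fit <- fit_global_diffusion(ds$table)
round(fit$diffusion$tc * 1e9, 2)   # ns
#> 7.29
```

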