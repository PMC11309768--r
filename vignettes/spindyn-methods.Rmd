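---
title: "Models and numerical methods in spindyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in spindyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindyn)
```

spindyn analyses backbone amide ^15^N spin relaxation and protein–RNA
binding data for double-stranded RNA-binding domains (dsRBDs), and ships a
synthetic-data generator with embedded ground truth so that every fitting
stage can be validated by recovery studies. This vignette is the package's
account of the underlying models, the numerical choices, and what the
passing tests do and do not demonstrate.

## Relaxation-rate fitting

Longitudinal and transverse rates (and their rotating-frame analogues) come
from mono-exponential fits of peak height against relaxation delay,
I(t) = I~0~ e^−Rt^, by Levenberg–Marquardt least squares. The initial guess
is deterministic — I~0~ = max height, R = log(I~first~/I~last~)/(t~last~ −
t~first~) clipped to [10^−3^, 10^3^] s^−1^ — so a fit of the same data is
bitwise repeatable. Delays acquired twice enter as separate observations
rather than being averaged, preserving the error model that duplicate
acquisitions imply. Negative fitted rates are reported (with a warning for
non-positive amplitudes) rather than clamped, because they are diagnostic
of artefacts.

Intensity noise is estimated from the duplicate delays as
σ = √(Σd~i~²/2m) over the m duplicate pairs. Whether the published analyses
pooled this across residues is not stated; both modes exist here, and the
default is per-residue with a pooled fallback when a residue's duplicate
pairs are incomplete. Rate uncertainties are Monte-Carlo: the best-fit curve
is resampled n = 500 times (seeded) with Gaussian noise of the estimated σ
and refitted; the spread of refitted rates is the reported uncertainty.

The steady-state heteronuclear nOe is the ratio of peak heights with and
without proton saturation; its error propagates the baseline-noise RMSDs of
the two spectra in quadrature. Constant-time CPMG data reduce to
R~2,eff~ = −ln(I~ν~/I~ref~)/T~relax~ with T~relax~ = 40 ms by default.
Dispersion is called only when the drop from the lowest to the highest CPMG
frequency exceeds k·σ (k = 2 by default) *and* an F-test at α = 0.05
prefers a two-parameter monotone surrogate R(ν) = a + b·ν~min~/ν over a
constant — both thresholds configurable, since the reference analyses
report only the qualitative flat outcome.

## Model-free analysis

The spectral density is the extended Lipari–Szabo form with up to three
time scales,

J(ω) = (2/5) Σ~j~ A~j~ [ S²τ~j~/(1+(ωτ~j~)²) + (1−S~f~²)τ′~f,j~/(1+(ωτ′~f,j~)²) +
(S~f~²−S²)τ′~s,j~/(1+(ωτ′~s,j~)²) ],  1/τ′ = 1/τ~j~ + 1/τ~internal~,

which reduces to the familiar two-time-scale extended form at τ~f~ = 0 and
to the original Lipari–Szabo form at S~f~² = 1. Isotropic tumbling has a
single global time τ~c~ (A = 1); the axially symmetric tensor contributes
three times built from (D~∥~, D~⊥~) with weights set by the angle between
the N–H vector and the symmetry axis. A fully anisotropic (ellipsoid)
tensor is out of scope, so comparisons with analyses that selected an
ellipsoid tensor are recovery-style rather than re-analysis-exact.

Rates follow the standard dipolar + CSA expressions with defaults
r~NH~ = 1.02 Å, Δσ~N~ = −172 ppm, γ~H~ = 2.6752×10^8^,
γ~N~ = −2.7126×10^7^ rad s^−1^ T^−1^ (all configurable through
`nmr_constants()`). R~ex~ is referenced to 600 MHz and scaled by
(B/B~ref~)² at other fields. Note one subtlety the tests encode: the
textbook extreme-narrowing nOe limit 1 + γ~H~/(2γ~N~) ≈ −3.93 holds only
for pure dipolar relaxation; with the default CSA the limit is ≈ −3.4, so
the test sets Δσ~N~ = 0 when asserting the closed form.

The model ladder is the conventional one: m0 (rigid), m1 {S²}, m2 {S², τ~e~},
m3 {S², R~ex~}, m4 {S², τ~e~, R~ex~}, m5 {S~f~², S², τ~s~}, m6 {S~f~², τ~f~,
S², τ~s~}, m7 {S~f~², S², τ~s~, R~ex~}, m8 {S~f~², τ~f~, S², τ~s~, R~ex~}.
Each model is optimized by bounded L-BFGS-B from five deterministic starting
points (reproducibility without global optimizers); the ordering constraint
S² ≤ S~f~² is structural (S² is parameterized as a fraction of S~f~²).
Selection uses the small-sample corrected AIC,
AICc = χ² + 2k + 2k(k+1)/(n−k−1), with ties broken toward fewer parameters.
With only 3–6 observables per residue the correction term matters: in
recovery studies on data generated from m2, plain AIC picks an R~ex~- or
extended-model variant on roughly one replicate in six, while AICc recovers
the generating model essentially always. Plain AIC remains available via
`criterion = "aic"`. Models whose parameter count exhausts the observation
count receive an infinite penalty, which is the honest small-sample
behaviour.

τ~c~ is initialized from the trimmed-mean R~2~/R~1~ ratio of rigid
candidates (nOe > 0.65) by a one-dimensional root solve of the rigid-limit
ratio, then refined by alternating (a) per-residue fits at fixed diffusion
and (b) diffusion optimization at fixed per-residue parameters, until the
summed χ² changes by less than 10^−6^ relative (at most 20 alternations;
non-convergence warns and returns the last iterate). Inside the alternation
the per-residue model set defaults to {m1, m2}: allowing R~ex~ during a
single-field global fit would let exchange absorb τ~c~ misfit and
de-identify the tensor.

## The HARD experiment and two-state exchange

The heteronuclear adiabatic relaxation dispersion experiment creates a spin
lock from trains of stretched hyperbolic-secant pulses HS*n*, with
amplitude A(t) = ω~1max~ sech(β((2t/T~p~)−1)^n^) and a frequency sweep over
[−bw/2, +bw/2] proportional to the running integral of A². Increasing *n*
flattens the amplitude profile and raises the time-averaged lock field at
fixed peak amplitude — that is the dispersion "dial". The pulse parameters
are not printed in the reference work; the defaults here are T~p~ = 16 ms
(the published relaxation delays are multiples of 16 ms), ω~1max~/2π =
2.5 kHz, bandwidth/2π = 5 kHz, 1024 waveform points, β = asech(0.01), all
configurable.

Magnetization is propagated through the 6×6 two-state Bloch–McConnell
generator with a dense matrix exponential per piecewise-constant waveform
step (compiled; unconditionally stable even at exchange rates far above the
step bandwidth). This direct propagation is the reference implementation;
the geometric-approximation shortcut used by some analyses is an
acceleration whose grids are not published, and is not reproduced here.
R~1ρ~ starts magnetization along +z, R~2ρ~ along +x (split across states by
population); the measured signal is the total magnetization projected onto
the ideally rotated (relaxation- and exchange-free) initial axis at each
pulse boundary, and the rate is a mono-exponential fit over the delay
ladder (defaults: 0–128 ms for R~1ρ~, 0–64 ms for R~2ρ~, integer multiples
of T~p~).

Two behaviours of this simulation deserve emphasis. First, *exchange-free
profiles are not flat across HS1…HS8*: the instantaneous tilt angle of the
effective field spends different fractions of the sweep near the transverse
plane for different *n*, so R~1ρ~ rises and R~2ρ~ falls with *n* even
without exchange — the ordering seen for every residue in published HARD
data. Exchange *inflates* the R~2ρ~ dispersion beyond this baseline.
Consequently the "no detectable exchange" sentinel in `fit_two_state()`
does not test flatness alone: it fits the exchange-free baseline model
(R~2g~ free, or anchored when known) and returns the sentinel when that
baseline already reproduces the data within noise (χ² below the 99.5%
quantile), or when the raw profiles are flat relative to noise.

Second, identifiability is limited. With a single field, a handful of HSn
conditions and ~2% rate noise, (p~B~, Δω, R~2g~, k~ex~) lie in a sloppy
valley: grossly different parameter sets reach equal χ². The fit therefore
searches a coarse grid (12 log-spaced k~ex~ × 10 p~B~ × 8 Δω points by
default) refined from the best three nodes by Nelder–Mead (Brent in one
dimension), in a bounded parameterization (k~ex~ log-uniform in
[10², 10⁶] s^−1^, p~B~ ∈ [0.01, 0.5] and Δω ∈ [0.2, 6] ppm through logistic
maps). When Δω is known — e.g. from observed shift differences — it can be
fixed (`fix_dw`), which together with a known intrinsic R~2~ (`fix_r2g`)
makes (p~B~, k~ex~) recoverable: the package's recovery tests condition on
those and then demand p~B~ within ±0.05 and k~ex~ within ×1.5. In the very
fast regime (k~ex~ far above the attainable lock field) only
p~B~(1−p~B~)/k~ex~ is data-constrained, so the classification-stability
study additionally fixes p~B~ (`fix_pb`). Monte-Carlo parameter spreads are
seeded refits of noise-resampled best-fit curves (n = 500 by default).

Classification uses the published bins: k~ex~ < 5000 s^−1^ slow (4999 is
slow; 5000 falls in the next bin), 5000–50,000 fast, > 50,000 very fast;
p~B~ bins at 10/20/40%. Apo-versus-bound comparisons report
Δk~ex~ = k~ex~(bound) − k~ex~(apo), flagged above 10,000 s^−1^ with the
sign recorded as induced or quenched, and a missing-state marker when a
residue was fit in only one state. Printed "Hz" exchange rates are treated
as s^−1^ throughout.

Waveform discretization converges quadratically: at the default 1024 points
a step-halving changes the final magnetization by ~10^−4^ relative (the
optional `check_step` doubling test uses that tolerance), and reaching
10^−6^ would require ~8192 points. Fits use coarser waveforms (96–256
points) than simulations, which is well inside the quadratic regime.

## Binding analyses

The two-state complex concentration is the quadratic root
[PL] = ((P~t~+L~t~+K~d~) − √((P~t~+L~t~+K~d~)² − 4P~t~L~t~))/2. The NMR
titration isotherm fits (K~d~, Δδ~max~) to Δδ~obs~ = Δδ~max~([P]~t~+[L]~t~+
K~d~ − √(…))/(2[P]~t~); the response may be a peak-intensity change or a
chemical shift — both are accepted and labelled, without asserting they are
interchangeable. A fit whose titration never reaches the inflection region
(max [L]~t~ below the fitted K~d~, or response well short of saturation)
warns that K~d~ is poorly constrained — the situation extensive line
broadening produced in the reference titrations. Combined chemical-shift
perturbations use CSP = √(Δδ~H~² + (0.14·Δδ~N~)²); the nitrogen weight is
configurable because no CSP formula is printed in the source work.

The ITC forward model is the single-site Wiseman isotherm: after each
injection the cell concentrations follow the standard displaced-volume
dilution, the bound fraction Θ comes from the quadratic binding polynomial,
the cumulative heat is Q(i) = nΘ(i)M~t~(i)ΔH V~0~, and the per-injection
heat applies dQ(i) = Q(i) + (dV~i~/V~0~)(Q(i)+Q(i−1))/2 − Q(i−1). The first
0.4 µl injection is simulated but its heat discarded, mirroring analysis
practice; a constant dilution-heat offset is fitted by default. Cell and
syringe volumes are not printed in the source work, so defaults follow the
instrument class (200 µl cell, 2 µl injections) and are configurable.
ΔG = RT ln K~d~ and ΔS = (ΔH − ΔG)/T at the experiment temperature; an
enthalpy-driven binder with µM affinity therefore shows the negative ΔS
sign convention the tests check. Non-saturating thermograms (late heats
comparable to early ones) warn of wide confidence intervals rather than
failing.

## The synthetic-data generator

Every generator is a deterministic function of (truth, seed) and embeds its
ground truth in a sidecar record, so any downstream recovery test can be
rerun from the dataset alone. Defaults emulate the study conditions: the
inversion-recovery schedule 10, 30*, 50, 100, 200, 300, 450*, 600 ms (* =
duplicate, drawn independently); two-field 600/800 MHz R1/R2/nOe sets from
the model-free forward model; HARD R1ρ/R2ρ over a configurable HSn set with
the published delay ladders; flat and dispersive CPMG profiles; one-site
titration curves over an equivalents grid; and single-site thermograms with
one discardable 0.4 µl plus eighteen 2 µl injections. The default synthetic
protein has 68 observed core residues in the 159–227 window (one position
is skipped the way a proline lacks an amide) with S² = 0.85, τ~e~ = 50 ps,
τ~c~ = 7.3 ns, flanked by 12 terminal/loop residues at S² = 0.3.

Noise is Gaussian and relative (a fraction of the signal) by default, with
absolute-σ modes where they are natural (ITC heats). Real spectra are less
kind: line-broadening makes noise heteroscedastic across residues and
titration points, peaks overlap, and the reference analyses selected an
ellipsoid diffusion tensor that this package's axial ceiling cannot
express. Passing recovery tests therefore demonstrate the correctness and
internal consistency of the estimators under the stated noise model — not
that real spectra would yield the same per-residue values.

One calibration note: forward-predicting the default core truth
(S² = 0.85, τ~e~ = 50 ps, τ~c~ = 7.3 ns isotropic) gives a 600-MHz core
mean R~1~ of ≈1.58 s^−1^, about 10% above the published measured core
average of 1.43 s^−1^ — the expected imprint of the ellipsoid-versus-
isotropic gap and of real per-residue heterogeneity. The generator keeps
the published truth values rather than retuning them; tests assert
consistency with the forward model and the published order of magnitude.
The shipped `inst/extdata/synthetic_core_rates.csv` is a clearly labelled
*synthetic stand-in* for the study's deposited per-residue rate tables: it
is constructed so its core-window summary statistics equal the published
core averages, and exists to exercise the read → filter → aggregate path.

## Problem sizes and runtime choices

The test-suite and acceptance problem sizes are chosen to keep full runs in
the minutes range on a single core while preserving statistical power: ITC
recovery uses 100 seeded replicates; the global τ~c~ recovery uses 60
residues at two fields; model-free model-selection studies use 50
replicates; HARD recovery and classification studies use 10 seeded
replicates with 3 HSn conditions and 96-point fitting waveforms; Monte-
Carlo error loops in tests use reduced n (25–50) while the function
defaults remain n = 500. The RNA-duplex utility counts Watson–Crick and
G·U wobble pairs over the antiparallel register of maximal overlap and is
exact.

## Known limitations

* No ellipsoid diffusion tensor; no structure-based extraction of N–H
  vectors (they are an input table).
* No three-state exchange models, and no off-resonance R1ρ experiments
  beyond the HSn family.
* The titration stage fits residues independently; no global multi-residue
  fit.
* Homoscedastic relative noise only in the generators; real
  line-broadening-dependent noise is not modelled.
* The HARD (p~B~, Δω, R~2g~, k~ex~) surface is intrinsically sloppy at
  single-field desk scale; unconditioned four-parameter fits should be
  interpreted through the classification bins, not as point estimates.
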