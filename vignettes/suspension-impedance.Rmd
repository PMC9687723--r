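---
title: "Modelling low-frequency impedance of particle and cell suspensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling low-frequency impedance of particle and cell suspensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suspeis)
```

## The problem

Between roughly 10 and 1000 Hz, the impedance of an electrolytic cell is
dominated by electrical double layers (EDLs): the layer at the measuring
electrodes (electrode polarization) and, when particles or non-adherent
cells are suspended in the electrolyte, the many double layers that form
around the dispersed phase. Counterion polarization around the dispersed
phase produces the alpha dispersion. Electrode polarization is usually
treated as a nuisance that masks the sample; the approach implemented
here instead folds both phenomena into a small equivalent circuit and
summarises them in two scalar responses that track how much material is
suspended:

* the **dispersed medium index (DMi)** — a normalized magnitude spectrum,
  `(|Z|_suspension - |Z|_medium) / |Z|_medium`, needing nothing but
  arithmetic; and
* the **effective capacitance (Cef)** — a single capacitance derived from
  a fitted equivalent circuit, more robust but requiring optimization.

Either response, calibrated against known concentrations, yields an
estimator of cell or particle concentration usable for growth or
viability monitoring of non-adherent lines, where substrate-attachment
methods do not apply.

## The equivalent circuit

The model is a series constant phase element (CPE) feeding a three-way
parallel block:

```
Z(w) = Z_CPEs(w) + [ Z_Ce(w) || Rd || Z_CPEd(w) ]
Z_CPE(w) = 1 / (T (jw)^P),   Z_Ce(w) = 1 / (jw Ce)
```

with six parameters: `ts`, `ps` (bulk-suspension CPE), `ce` (electrode
double-layer capacitance), and `rd`, `td`, `pd` (resistance and CPE of
the dispersed-medium double layers). A CPE interpolates between an ideal
resistor (`P = 0`) and an ideal capacitor (`P = 1`); its phase is
`-P * 90` degrees at every frequency, the signature of a rough,
heterogeneous, or distributed interface.

**Why the dispersed branch is a resistor shunted by a CPE.** The package
unifies the branch into a capacitance with the Hsu–Mansfeld form
`Cd = (Td * Rd^(1 - Pd))^(1/Pd)`, which is the effective capacitance of
an R-parallel-CPE relaxation element (the constant-phase generalization
of a Cole–Cole arc); the total is then `Cef = Ce + Cd`, and capacitances
add only when the branches sit in parallel. The alternative series
arrangement (`Rd + CPEd`) was implemented and rejected during
development: it fails to reproduce the expected spectral orderings in the
lower half of the band (raising `pd` should lower `|Z|` everywhere below
about 100 Hz, but the series variant crosses over near 65 Hz), and it
puts a nearly vertical capacitive line where measurements of such cells
show a depressed semicircle at the high-frequency end (the R‖CPE
signature) with an inclined, diffusion-like spike at low frequency. The
topology lives in one function (`circuit_impedance()`), so a different
arrangement can be swapped in without touching the fitting machinery.

Any passive network of this form has phase in `[-90, 0]` degrees and
`|Z| -> 0` as frequency grows; both properties are enforced as tests.

```{r}
p <- circuit_params(ts = 0.1, ps = 0.3, ce = 1e-6, rd = 1e4,
                    td = 1e-6, pd = 0.7)
s <- circuit_impedance(p, log_freq_grid())
s
effective_capacitance(p) * 1e6   # uF
```

Units are SI throughout (`F`, `F s^(P-1)`, `Ohm`, `Hz`); microfarads and
degrees appear only in printed output and reports. The conversion
`w = 2 pi f` happens once per evaluation; `pd = 0` is rejected rather
than special-cased because the unification exponent `1/pd` is singular
there (fitted exponents for real suspensions sit around 0.71–0.81, far
from the boundary).

## Double-layer physics

For physical interpretation of fitted capacitances, `gcs_capacitance()`
implements the Gouy–Chapman–Stern model: a compact (Stern) layer and a
diffuse layer in series,

```
1/C_DL = x_OHP / (eps eps0)
       + 1 / [ sqrt(2 eps eps0 z^2 e^2 n0 / (kB T)) * cosh(z e psi / (2 kB T)) ]
```

The diffuse term stiffens with ionic strength and with surface potential:
a more highly charged surface compacts its diffuse layer. Physical
constants are fixed at CODATA 2018 values; the relative permittivity is
treated as constant across both layers, a simplification that overstates
the Stern-layer permittivity where dipoles saturate. Note the division by
`kB T` inside the square root — dimensional analysis forces it, and the
implementation uses this standard form.

```{r}
gcs_capacitance(x_ohp = 0, eps_r = 78.5,
                n0 = ionic_number_density(0.154),  # physiological saline
                z_val = 1, psi = 0, temp_K = 310)  # F/m^2
```

## Fitting: estimator design

`fit_circuit()` minimizes the stacked real and imaginary residuals of the
circuit model against an observed spectrum with a bounded
Levenberg–Marquardt trust-region solver (`minpack.lm::nls.lm`). Design
choices that matter:

* **Weighting.** Residuals are divided by `|Z_obs|` per frequency
  (`"modulus"`, the default). `|Z|` spans about a decade over the band;
  unweighted residuals let the low-frequency points dominate and, in
  simulation, degrade the precision of the recovered `Cef` several-fold.
  Unit weighting remains available for comparison. Any zero-residual
  minimum is a minimum under either weighting.
* **Parameterization and bounds.** `ts`, `ce`, `rd`, `td` are optimized
  as log10 values; exponents stay linear. Box bounds (defaults:
  magnitudes in `[1e-12, 10]` F-equivalents, `rd` in `[1, 1e9]` Ohm,
  `ps` in `[0, 1]`, `pd` in `[0.05, 1]`) keep every iterate physical —
  a plain Levenberg–Marquardt without bounds can wander into negative or
  super-capacitive territory on noisy spectra.
* **Initialization.** The heuristic guess reads `ce` from the
  highest-frequency imaginary part (`ce ~ -1/(w Im Z)`), `rd` from the
  real-axis extent of the Nyquist arc, and nominal values for the
  dispersed CPE (`td = 1e-6`, `pd = 0.75`). The series CPE is *not* read
  from the raw low-frequency phase — the parallel block dominates there —
  but from the remainder after subtracting the estimated block.
* **Multistart.** CPE circuits have well-known local minima (e.g. `pd`
  pinned at 1 while `ce` absorbs the branch). The fit launches
  `n_starts = 8` seeded starts: the heuristic guess plus jittered copies
  (±1.5 decades on `ts`, ±1 on `ce` and `rd`, ±0.5 on `td`, ±0.3/±0.15 on
  the exponents). Lowest final cost wins; ties break toward the earlier
  start. The jitter widths were set so that every bundled reference
  generator is recovered to machine precision from noiseless spectra
  across independent jitter seeds; one generator (48 µm at 200/µL) has a
  contaminated high-frequency `ce` estimate and genuinely needs the ±1
  decade net on `ce`.
* **Convergence.** `ftol = ptol = 1e-15` by default so that noiseless
  fits bottom out near machine precision — necessary for the closed-loop
  check below, where `R^2 = 1` is asserted to `1e-10`. Hitting the
  iteration cap returns `converged = FALSE` rather than an error; only a
  failure of every start raises.
* **Identifiability.** On a two-decade band the series CPE and `ce` trade
  off at the band edges; cost is reported, but per-parameter uncertainty
  quantification is deliberately out of scope.

Spectra shorter than 4 frequencies are rejected (six parameters against
`2n` residuals), and fits are invariant to input row order because the
spectrum container sorts by frequency on construction.

## DMi conventions

Replicate aliquots are averaged per frequency (`average_spectra()`, which
also reports the per-frequency spread as a percentage) *before* the index
is computed; with shared grids the two orders of operation agree exactly.
Grids are expected to be identical — sweeps from one instrument are —
and mismatches raise unless log-frequency interpolation is explicitly
enabled. The scalar reported for calibration defaults to 50 Hz, where
suspensions separate most clearly; a 50-point log grid has no point at
exactly 50 Hz, so `dmi_at()` returns stored values on-grid and otherwise
interpolates linearly in log-frequency, flagging the result.

## Calibration

`fit_calibration()` is unweighted ordinary least squares of the response
(DMi scalar, or `Cef` in farads) on concentration; the slope is the
sensitivity, in response units per (count/µL). Linear-in-concentration is
the minimal model consistent with the near-linear behaviour both
responses show over 25–400 counts/µL; a log-concentration regressor is
available for responses that saturate. `predict_concentration()` inverts
the line and flags extrapolation beyond the calibrated range. At least
three points and a non-constant response are required.

## The synthetic generator: what it does and does not emulate

`generate_spectrum()` multiplies the forward model by
`1 + eps_re + 1i*eps_im` with independent Gaussians of standard deviation
`relative_sigma` (default 1%) — proportional noise, because instrument
error tracks signal level across the decade-wide `|Z|` range. The
generator is seeded and leaves the caller's RNG untouched.
`generate_concentration_series()` maps concentrations through a trend
function; the default (`ce_trend()`) interpolates `ce` linearly between
the bundled endpoints for the chosen particle diameter and holds the
other parameters at per-diameter medians, making `Cef` exactly linear in
concentration — the idealized case a calibration assumes.

What this does *not* capture: pipetting error between aliquots (real
replicate spreads reach tens of percent at low counts, far beyond
instrument noise), electrode drift and fouling, temperature excursions,
particle sedimentation or aggregation, and any real nonlinearity of the
concentration trend. Passing closed-loop tests therefore demonstrate
estimator correctness under the stated noise model, not field
performance on measured suspensions.

## Validation problem sizes

The test suite exercises: forward-model agreement with an independent
complex-arithmetic oracle to 1e-12 relative on 100 random parameter draws
over 50 frequencies; noiseless parameter recovery to below 1% relative
error for all 15 bundled generators on the 50-point 10–1000 Hz grid;
recovery of `Cef` within 5% under 1% proportional noise across 15
generators × 20 seeds (aggregate success rate above 90%, measured ~96%);
and a full generate–fit–calibrate–predict loop over the five-step
half-fold dilution series (400 down to 25 counts/µL), holding out the
middle concentration, with median held-out error within 10% over 20
seeds at 1% noise and an exact (`1 - R^2 < 1e-10`) noiseless closure.

## Known limitations

* The circuit topology is an inference from the unified-capacitance
  algebra and the qualitative shape of suspension spectra; headline
  capacitance values (`Cef`) depend only on the unification formula, but
  simulated spectral shapes would change under a different arrangement.
* `Cef` and DMi both saturate as the dispersed-phase volume fraction
  grows; DMi in particular stops resolving concentration once the volume
  fraction exceeds a few times `1e-4`.
* The estimator reports no confidence intervals; multistart cost is the
  only fit diagnostic.
* No Kramers–Kronig consistency check is applied to input spectra;
  non-causal or drifting measurements will fit to *something*.
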