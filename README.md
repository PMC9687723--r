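# suspeis

Low-frequency electrical impedance spectroscopy (EIS) analysis of
particles and non-adherent cells in electrolytic suspension.

Between 10 and 1000 Hz, the impedance of an electrolytic cell is ruled
by electrical double layers: electrode polarization at the measuring
electrodes, and the many double layers that form around suspended
particles or cells (the alpha dispersion). Substrate-attachment assays
(ECIS-style) cannot monitor non-adherent lines — blood cells, leukemia
lines, stem cells — so this package instead extracts concentration
information from exactly those double-layer signals. It is aimed at
researchers running potentiostat sweeps of suspensions who want a
calibrated, scriptable estimate of how much material is in the chamber.

## What it computes

Two scalar responses per suspension, both monotone in concentration:

**Dispersed medium index (DMi)** — the suspension's magnitude spectrum
normalized by the pure liquid medium measured in the same cell,

    DMi(f) = (|Z|_S(f) − |Z|_LM(f)) / |Z|_LM(f)

pure arithmetic, no fitting; reported at 50 Hz by default.

**Effective capacitance (Cef)** — a six-parameter equivalent circuit,

    Z(ω) = 1/(Ts (jω)^Ps)  +  [ 1/(jω Ce)  ∥  Rd  ∥  1/(Td (jω)^Pd) ]

(a bulk-suspension constant phase element in series with the electrode
double-layer capacitance, the latter in parallel with the
dispersed-medium double layers as an R‖CPE relaxation), is fitted to the
complex spectrum by bounded Levenberg–Marquardt least squares, and the
double-layer capacitances are unified via the Hsu–Mansfeld form:

    Cef = Ce + (Td · Rd^(1−Pd))^(1/Pd)

Either response, regressed on known concentrations
(`fit_calibration()`), gives a sensitivity (slope), an R², and an
inverse estimator of concentration (`predict_concentration()`).

Supporting modules: Gouy–Chapman–Stern double-layer capacitances for
physical interpretation (`gcs_capacitance()`), suspension bookkeeping
(`volume_fraction()`, `serial_dilution()`, `particle_count()`), seeded
synthetic spectrum generation (`generate_spectrum()`,
`generate_concentration_series()`), CSV spectrum I/O in rectangular and
polar dialects, JSON reports, and a command-line wrapper
(`inst/cli/suspeis.R`) with `simulate`, `fit`, `dmi`, `calibrate`,
`gcs`, and `vf` commands.

## Worked example

Simulate a 6 µm-particle suspension at 25/µL (bundled reference
parameters), fit the circuit back at 1 % proportional noise, then run a
five-point half-fold dilution series through the whole
generate–fit–calibrate–predict loop:

```r
library(suspeis)

truth <- circuit_params(ts = 0.86e-3, ps = 0.31, ce = 0.57e-6,
                        rd = 3815, td = 9.9e-7, pd = 0.73)
obs <- generate_spectrum(truth, log_freq_grid(), noise_model(0.01, seed = 42))
fit_circuit(obs)
#> Equivalent-circuit fit
#> Equivalent-circuit parameters:
#>   bulk CPE:       Ts = 0.001203 F s^(P-1), Ps = 0.279
#>   electrode:      Ce = 5.39e-07 F (0.539 uF)
#>   dispersed EDL:  Rd = 3890 Ohm, Td = 1.011e-06 F s^(P-1), Pd = 0.747
#>   Cef = 6.932e-07 F (0.693 uF)   cost = 0.01054 (modulus weighting)
#>   winning start 7, 15 iterations
```

The fitted effective capacitance, 0.693 µF, recovers the generator's
true 0.696 µF to 0.4 % despite the noise; `cost` is the final weighted
residual sum of squares across the 50 spectrum points.

```r
concs <- sort(serial_dilution(400, 5, 2))   # 25 50 100 200 400 /uL
series <- generate_concentration_series(concs, trend = ce_trend(6),
                                        noise = noise_model(0.01, seed = 7))
cefs <- sapply(seq_along(series), function(k)
  fit_circuit(series[[k]]$spectrum, fit_config(seed = k))$cef)
fit_calibration(concs, cefs)
#> Calibration curve (5 points, conc regressor):
#>   sensitivity (slope): 5.244e-10 per (count/uL)
#>   intercept: 7.092e-07   R^2: 0.9409
```

The slope says each additional particle/µL adds ~0.52 pF of effective
capacitance for this particle size; at zero noise the same loop returns
R² = 1 exactly. Inverting the calibration for a new spectrum
(`predict_concentration()`) returns the concentration estimate and flags
extrapolation outside the calibrated 25–400 /µL range.

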