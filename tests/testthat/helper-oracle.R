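# Independent brute-force oracles, deliberately written on a different
# route than the package: CPE impedance in polar form (modulus/argument),
# parallel combination as reciprocal-sum. No package code is reused.

oracle_cpe <- function(T, P, f) {
  w <- 2 * pi * f
  complex(modulus = 1 / (T * w^P), argument = -P * pi / 2)
}

oracle_circuit <- function(p, f) {
  w <- 2 * pi * f
  z_s <- oracle_cpe(p$ts, p$ps, f)
  z_ce <- complex(modulus = 1 / (w * p$ce), argument = -pi / 2)
  z_d <- 1 / (1 / p$rd + 1 / oracle_cpe(p$td, p$pd, f))  # Rd shunted by CPEd
  z_s + 1 / (1 / z_ce + 1 / z_d)                          # in parallel with Ce
}

# Random valid parameter draw over the regimes seen in suspension fits
rand_params <- function() {
  circuit_params(
    ts = 10^runif(1, -4, -1),
    ps = runif(1, 0.05, 0.95),
    ce = 10^runif(1, -7, -5),
    rd = 10^runif(1, 2.5, 4.5),
    td = 10^runif(1, -7, -5.5),
    pd = runif(1, 0.3, 0.95)
  )
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

clamp_unit <- function(x) min(max(x, 0), 1)

# per-parameter relative error between two circuit_params
param_rel_err <- function(est, truth) {
  e <- unlist(est)
  t <- unlist(truth)
  max(abs(e - t) / abs(t))
}
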