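ref_row <- function(i) {
  r <- reference_fits()[i, ]
  circuit_params(r$ts, r$ps, r$ce, r$rd, r$td, r$pd)
}

test_that("residuals vanish at the generating parameters and count 2n", {
  p <- ref_row(1)
  obs <- circuit_impedance(p, log_freq_grid(n = 30))
  r <- circuit_residuals(p, obs, "modulus")
  expect_length(r, 60)
  expect_lt(max(abs(r)), 1e-14)
  q <- rand_params()
  expect_length(circuit_residuals(q, obs, "unit"), 60)
})

test_that("modulus weighting divides unit residuals by |Z_obs| pointwise", {
  p <- ref_row(4)
  obs <- circuit_impedance(ref_row(1), log_freq_grid(n = 25))
  unit <- circuit_residuals(p, obs, "unit")
  modw <- circuit_residuals(p, obs, "modulus")
  w <- rep(Mod(obs$z), 2)
  expect_equal(modw, unit / w, tolerance = 1e-14)
})

test_that("fitting a noiseless spectrum from the truth is a fixed point", {
  truth <- ref_row(3)
  obs <- circuit_impedance(truth, log_freq_grid())
  fit <- fit_circuit(obs, fit_config(n_starts = 1), init = truth)
  expect_true(fit$converged)
  expect_lt(fit$cost, 1e-20)
  expect_lt(param_rel_err(fit$params, truth), 1e-6)
  expect_equal(fit$cef, effective_capacitance(truth), tolerance = 1e-6)
})

test_that("multistart recovers truth from a +/-30% perturbed start", {
  truth <- ref_row(1)  # 6 um, lowest concentration
  obs <- circuit_impedance(truth, log_freq_grid())
  set.seed(2024)
  pert <- circuit_params(
    ts = truth$ts * runif(1, 0.7, 1.3),
    ps = clamp_unit(truth$ps * runif(1, 0.7, 1.3)),
    ce = truth$ce * runif(1, 0.7, 1.3),
    rd = truth$rd * runif(1, 0.7, 1.3),
    td = truth$td * runif(1, 0.7, 1.3),
    pd = clamp_unit(truth$pd * runif(1, 0.7, 1.3))
  )
  fit <- fit_circuit(obs, fit_config(n_starts = 8, seed = 99), init = pert)
  expect_lt(param_rel_err(fit$params, truth), 0.01)
})

test_that("the fit result is exposed with cost, winner index and derived Cef", {
  truth <- ref_row(2)
  obs <- generate_spectrum(truth, log_freq_grid(),
                           noise = noise_model(0.01, seed = 3))
  fit <- fit_circuit(obs, fit_config(n_starts = 4, seed = 7))
  expect_s3_class(fit$params, "circuit_params")
  expect_gte(fit$cost, 0)
  expect_true(fit$start_index %in% 1:4)
  expect_equal(fit$cef, effective_capacitance(fit$params))
  expect_named(coef(fit), c("ts", "ps", "ce", "rd", "td", "pd"))
})

test_that("spectra too short for six parameters are rejected", {
  p <- ref_row(1)
  obs <- circuit_impedance(p, c(10, 100, 1000))
  expect_error(fit_circuit(obs), "at least 4")
})

test_that("the heuristic guess is always in bounds and lands in the truth's basin", {
  b <- default_bounds()
  for (i in c(1, 5, 8, 15)) {
    truth <- ref_row(i)
    obs <- circuit_impedance(truth, log_freq_grid())
    g <- initial_guess(obs)
    gv <- unlist(g)
    expect_true(all(gv >= b$lower[names(gv)] & gv <= b$upper[names(gv)]))
    fit <- fit_circuit(obs, fit_config(n_starts = 1))
    expect_lt(param_rel_err(fit$params, truth), 1e-4)
  }
  # one generator (48 um, 200/uL) whose guess needs the default multistart
  truth <- ref_row(12)
  obs <- circuit_impedance(truth, log_freq_grid())
  fit <- fit_circuit(obs, fit_config(n_starts = 8, seed = 1))
  expect_lt(param_rel_err(fit$params, truth), 1e-4)
  # a bare monotone |Z| spectrum still yields finite positive guesses
  f <- log_freq_grid(n = 10)
  flat <- eis_spectrum(f, complex(real = 1000 / f, imaginary = -100 / f))
  g <- initial_guess(flat)
  expect_true(all(is.finite(unlist(g))) && all(unlist(g) > 0))
})

test_that("fits are invariant to the input row order", {
  truth <- ref_row(7)
  f <- log_freq_grid(n = 40)
  z <- circuit_impedance(truth, f)$z
  scramble <- sample(seq_along(f))
  obs1 <- eis_spectrum(f, z)
  obs2 <- eis_spectrum(f[scramble], z[scramble])
  cfg <- fit_config(n_starts = 2, seed = 5)
  expect_equal(unlist(fit_circuit(obs1, cfg)$params),
               unlist(fit_circuit(obs2, cfg)$params), tolerance = 1e-12)
})

test_that("modulus weighting keeps any zero-residual minimum in place", {
  truth <- ref_row(9)
  obs <- circuit_impedance(truth, log_freq_grid())
  for (wgt in c("modulus", "unit")) {
    fit <- fit_circuit(obs, fit_config(weighting = wgt, n_starts = 1),
                       init = truth)
    expect_lt(fit$cost, 1e-20)
    expect_lt(param_rel_err(fit$params, truth), 1e-8)
  }
})

test_that("fit configuration validates bounds and counts", {
  expect_error(fit_config(n_starts = 0), "n_starts")
  b <- default_bounds(); b$lower[["pd"]] <- -0.5
  expect_error(fit_config(bounds = b), "\\[0, 1\\]")
  b <- default_bounds(); b$lower[["ts"]] <- 2; b$upper[["ts"]] <- 1
  expect_error(fit_config(bounds = b), "below")
})
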