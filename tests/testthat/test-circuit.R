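test_that("CPE impedance reduces to ideal elements at the exponent limits", {
  # P = 0: ideal resistor of resistance 1/T, at any frequency
  for (f in c(10, 50, 1000)) {
    expect_equal(cpe_impedance(1, 0, f), 1 + 0i)
    expect_equal(cpe_impedance(4, 0, f), 0.25 + 0i)
  }
  # P = 1: ideal capacitor, Z = -i/(wC), phase exactly -90 deg
  C <- 2.2e-6
  f <- 130
  z <- cpe_impedance(C, 1, f)
  expect_equal(z, -1i / (2 * pi * f * C), tolerance = 1e-14)
  expect_equal(Arg(z) * 180 / pi, -90)
})

test_that("CPE impedance matches the polar-form evaluation", {
  z <- cpe_impedance(1e-6, 0.7, 10)
  expect_equal(Mod(z), 1 / (1e-6 * (2 * pi * 10)^0.7), tolerance = 1e-14)
  expect_equal(Arg(z) * 180 / pi, -63, tolerance = 1e-12)
  # rectangular vs polar route over a frequency sweep
  f <- log_freq_grid(n = 20)
  expect_equal(cpe_impedance(3e-4, 0.42, f), oracle_cpe(3e-4, 0.42, f),
               tolerance = 1e-14)
})

test_that("CPE rejects invalid constants and frequencies", {
  expect_error(cpe_impedance(0, 0.5, 10), "positive")
  expect_error(cpe_impedance(-1, 0.5, 10), "positive")
  expect_error(cpe_impedance(1e-6, 1.2, 10), "\\[0, 1\\]")
  expect_error(cpe_impedance(1e-6, 0.5, 0), "positive")
  expect_error(cpe_impedance(1e-6, 0.5, -5), "positive")
})

test_that("CPE log-log magnitude slope equals -P and phase is -P*90 everywhere", {
  for (P in c(0.15, 0.5, 0.87)) {
    f <- c(20, 20 * (1 + 1e-6))
    z <- cpe_impedance(1e-5, P, f)
    slope <- diff(log(Mod(z))) / diff(log(2 * pi * f))
    expect_equal(slope, -P, tolerance = 1e-6)
    expect_equal(Arg(cpe_impedance(1e-5, P, c(10, 100, 1000))) * 180 / pi,
                 rep(-P * 90, 3), tolerance = 1e-12)
  }
})

test_that("circuit parameter constructor enforces invariants", {
  expect_s3_class(circuit_params(0.1, 0.3, 1e-6, 1e4, 1e-6, 0.7),
                  "circuit_params")
  expect_error(circuit_params(0, 0.3, 1e-6, 1e4, 1e-6, 0.7), "positive")
  expect_error(circuit_params(0.1, 1.3, 1e-6, 1e4, 1e-6, 0.7), "\\[0, 1\\]")
  expect_error(circuit_params(0.1, 0.3, 1e-6, -1, 1e-6, 0.7), "positive")
  expect_error(circuit_impedance(circuit_params(0.1, 0.3, 1e-6, 1e4, 1e-6, 0.7),
                                 numeric(0)), "non-empty")
})

test_that("full-circuit impedance agrees with the brute-force oracle", {
  set.seed(42)
  f <- log_freq_grid(n = 50)
  for (i in 1:10) {
    p <- rand_params()
    z_pkg <- circuit_impedance(p, f)$z
    z_orc <- oracle_circuit(p, f)
    expect_lt(max(Mod(z_pkg - z_orc) / Mod(z_orc)), 1e-12)
  }
})

test_that("full-circuit spectrum is passive and shorts at high frequency", {
  set.seed(7)
  for (i in 1:20) {
    p <- rand_params()
    s <- circuit_impedance(p, log_freq_grid(n = 30))
    ph <- impedance_phase(s)
    expect_true(all(ph >= -90 - 1e-9 & ph <= 1e-9))
  }
  p <- circuit_params(0.1, 0.3, 1e-6, 1e4, 1e-6, 0.7)
  expect_lt(Mod(circuit_impedance(p, 1e12)$z), 1e-2)
})

test_that("|Z| decreases with frequency for the reference simulation cases", {
  cases <- simulation_cases()
  for (i in seq_len(nrow(cases))) {
    s <- circuit_impedance(cases[i, ], log_freq_grid())
    expect_true(all(diff(impedance_magnitude(s)) < 0))
    ph <- impedance_phase(s)
    expect_true(all(ph > -90 & ph < 0))
  }
})

test_that("raising the dispersed-medium exponent lowers low-frequency |Z|", {
  cases <- simulation_cases()
  f <- log_freq_grid(10, 99, n = 20)
  mag_a <- impedance_magnitude(circuit_impedance(cases[cases$case == "a", ], f))
  mag_c <- impedance_magnitude(circuit_impedance(cases[cases$case == "c", ], f))
  expect_true(all(mag_c < mag_a))
})

test_that("dispersed capacitance has the right limits and monotonicity", {
  # Pd = 1: the CPE is an ideal capacitor, Cd = Td exactly
  expect_identical(dispersed_capacitance(12345, 3.3e-7, 1), 3.3e-7)
  expect_error(dispersed_capacitance(1e4, 1e-6, 0), "singular")
  expect_error(dispersed_capacitance(-1, 1e-6, 0.5), "positive")
  # strictly increasing in Td and Rd
  expect_gt(dispersed_capacitance(1e4, 2e-6, 0.7),
            dispersed_capacitance(1e4, 1e-6, 0.7))
  expect_gt(dispersed_capacitance(2e4, 1e-6, 0.7),
            dispersed_capacitance(1e4, 1e-6, 0.7))
})

test_that("effective capacitance composes limits and orders the reference cases", {
  # limits compose: Ce = 0, Pd = 1 gives Cef = Td exactly
  expect_identical(effective_capacitance(list(ce = 0, rd = 5e3, td = 7e-7, pd = 1)),
                   7e-7)
  cases <- simulation_cases()
  cef <- vapply(seq_len(nrow(cases)),
                function(i) effective_capacitance(cases[i, ]), numeric(1))
  # strictly increasing a < b < c < d < e (Pd then Ce increasing)
  expect_true(all(diff(cef) > 0))
  # strictly increasing in Pd on [0.7, 0.9] at the fixed branch values
  pd_grid <- seq(0.7, 0.9, by = 0.01)
  cd <- dispersed_capacitance(1e4, 1e-6, pd_grid)
  expect_true(all(diff(cd) > 0))
})
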