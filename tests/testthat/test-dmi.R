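make_mag <- function(f, m) magnitude_spectrum(f, m)

test_that("DMi of the medium against itself is zero; ratios map through", {
  f <- log_freq_grid(n = 12)
  m <- make_mag(f, 500 + 100 * log10(f))
  expect_equal(compute_dmi(m, m)$dmi, rep(0, 12))
  dbl <- make_mag(f, 2 * m$mag_ohm)
  expect_equal(compute_dmi(dbl, m)$dmi, rep(1, 12))
  hlf <- make_mag(f, 0.5 * m$mag_ohm)
  expect_equal(compute_dmi(hlf, m)$dmi, rep(-0.5, 12))
})

test_that("DMi is invariant under common rescaling of both spectra", {
  set.seed(11)
  f <- log_freq_grid(n = 15)
  s <- make_mag(f, exp(runif(15, 5, 8)))
  m <- make_mag(f, exp(runif(15, 5, 8)))
  base <- compute_dmi(s, m)$dmi
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    scaled <- compute_dmi(make_mag(f, k * s$mag_ohm),
                          make_mag(f, k * m$mag_ohm))$dmi
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("averaging replicates commutes with the DMi computation", {
  f <- log_freq_grid(n = 10)
  reps_s <- lapply(1:3, function(i) make_mag(f, 1000 + 50 * i + f * 0.1))
  m <- make_mag(f, rep(900, 10))
  avg_first <- compute_dmi(average_spectra(reps_s), m)$dmi
  per_freq_mean <- rowMeans(sapply(reps_s, function(r) r$mag_ohm))
  expect_equal(avg_first, (per_freq_mean - m$mag_ohm) / m$mag_ohm)
  # spread reported as a percentage of the mean
  sd_pct <- attr(average_spectra(reps_s), "sd_percent")
  expect_length(sd_pct, 10)
  expect_true(all(sd_pct > 0))
})

test_that("DMi accepts complex spectra and coerces to magnitudes", {
  p <- circuit_params(0.1, 0.3, 1e-6, 1e4, 1e-6, 0.7)
  s <- circuit_impedance(p, log_freq_grid(n = 20))
  d <- compute_dmi(s, s)
  expect_equal(d$dmi, rep(0, 20))
})

test_that("scalar extraction returns stored values on-grid and interpolates off-grid", {
  f <- c(10, 25, 50, 100, 400)
  d <- compute_dmi(make_mag(f, c(12, 11, 10, 9, 8) * 100),
                   make_mag(f, rep(1000, 5)))
  on <- dmi_at(d, 50)
  expect_equal(as.numeric(on), d$dmi[3])
  expect_false(attr(on, "interpolated"))
  # constant spectrum interpolates to the constant anywhere in range
  dc <- compute_dmi(make_mag(f, rep(1500, 5)), make_mag(f, rep(1000, 5)))
  mid <- dmi_at(dc, 37)
  expect_equal(as.numeric(mid), 0.5)
  expect_true(attr(mid, "interpolated"))
  # linear-in-log(f) index: the log-midpoint query is the mean of neighbours
  f2 <- c(10, 100)
  d2 <- compute_dmi(make_mag(f2, c(1100, 1300)), make_mag(f2, c(1000, 1000)))
  expect_equal(as.numeric(dmi_at(d2, sqrt(10 * 100))), mean(c(0.1, 0.3)),
               tolerance = 1e-12)
  expect_error(dmi_at(d, 5), "outside")
  expect_error(dmi_at(d, 1000), "outside")
})

test_that("grid mismatch errors unless interpolation is enabled", {
  f1 <- log_freq_grid(10, 1000, 10)
  f2 <- log_freq_grid(12, 900, 10)
  s <- make_mag(f1, rep(1200, 10))
  m <- make_mag(f2, rep(1000, 10))
  expect_error(compute_dmi(s, m), "interpolate")
  d <- compute_dmi(s, m, interpolate = TRUE)
  expect_equal(d$dmi, rep(0.2, length(d$frequency_hz)), tolerance = 1e-12)
  # disjoint ranges cannot be reconciled
  expect_error(compute_dmi(make_mag(c(1, 2), c(10, 10)),
                           make_mag(c(100, 200), c(10, 10)),
                           interpolate = TRUE), "overlap")
})
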