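test_that("resample_1nm interpolates linearly and guards its range", {
  s <- spectrum(seq(300, 900, by = 10), rep(5, 61), "relative")
  r <- resample_1nm(s, 360, 830)
  expect_identical(r$wavelength_nm, as.numeric(360:830))
  expect_true(all(r$values == 5))
  expect_identical(r$units, "relative")

  ramp <- spectrum(seq(300, 900, by = 10), seq(300, 900, by = 10), "counts")
  r2 <- resample_1nm(ramp, 360, 830)
  expect_equal(r2$values, as.numeric(360:830), tolerance = 1e-12)

  narrow <- spectrum(400:700, rep(1, 301), "relative")
  expect_error(resample_1nm(narrow, 360, 830), "outside source support")

  # idempotent on 1-nm-gridded input
  r3 <- resample_1nm(r2, 400, 700)
  expect_equal(resample_1nm(r3, 400, 700)$values, r3$values)
})

test_that("median_filter matches the brute-force truncated-window oracle", {
  set.seed(11)
  x <- stats::rnorm(50)
  x[25] <- 1e6                                   # single-sample spike
  for (order in c(1, 2, 3, 8)) {
    got <- median_filter(spectrum(1:50 + 299, x, "counts"), order)
    expect_equal(got$values, median_filter_oracle(x, order),
                 info = paste("order", order))
  }
  # spike in a flat background is removed entirely
  flat <- rep(1, 50); flat[20] <- 1e6
  out <- median_filter(spectrum(301:350, flat, "counts"), 8)
  expect_true(all(out$values == 1))
  # constant input is unchanged; output never leaves [min, max] of input
  cst <- median_filter(flat_spectrum(3), 8)
  expect_true(all(cst$values == 3))
  rnd <- stats::rnorm(200)
  mf <- median_filter(spectrum(1:200, rnd, "counts"), 8)
  expect_true(all(mf$values >= min(rnd) & mf$values <= max(rnd)))
  # order 1 on [1, 9, 1]: two-point windows under the truncation rule
  expect_equal(median_filter(spectrum(1:3, c(1, 9, 1), "counts"), 1)$values,
               median_filter_oracle(c(1, 9, 1), 1))
})

test_that("l2_normalize returns a unit vector and the scale", {
  n <- l2_normalize(spectrum(c(500, 501), c(3, 4), "relative"))
  expect_equal(n$spectrum$values, c(0.6, 0.8))
  expect_equal(n$norm, 5)
  again <- l2_normalize(n$spectrum)
  expect_equal(again$norm, 1, tolerance = 1e-12)
  expect_error(l2_normalize(spectrum(1:5, rep(0, 5), "counts")), "all-zero")
})

test_that("band_irradiance is a trapezoidal integral with unit checks", {
  vis <- wavelength_band(400, 800, "VIS")
  flat <- flat_spectrum(0.001, 280, 900, units = "irradiance_W_m2_nm")
  expect_equal(band_irradiance(flat, vis), 0.4, tolerance = 1e-12)
  expect_equal(band_irradiance(
    flat_spectrum(0, 280, 900, units = "irradiance_W_m2_nm"), vis), 0)
  expect_error(band_irradiance(flat_spectrum(1), vis), "irradiance units")
  expect_error(
    band_irradiance(flat_spectrum(1, 900, 950, "irradiance_W_m2_nm"), vis),
    "overlap")

  # triangle on a coarse grid vs fine Riemann refinement
  tri <- spectrum(c(400, 430, 500, 650, 800),
                  c(0, 2, 0.5, 3, 0), "irradiance_W_m2_nm")
  fine <- seq(400, 800, by = 0.1)
  fv <- stats::approx(tri$wavelength_nm, tri$values, fine)$y
  oracle <- sum((fv[-1] + fv[-length(fv)]) / 2 * 0.1)
  expect_equal(band_irradiance(tri, vis), oracle, tolerance = 1e-6)

  # additive over adjacent disjoint bands
  s <- spectrum(360:830, stats::runif(471), "irradiance_W_m2_nm")
  expect_equal(band_irradiance(s, vis),
               band_irradiance(s, wavelength_band(400, 600)) +
                 band_irradiance(s, wavelength_band(600, 800)),
               tolerance = 1e-12)
})

test_that("normalize_at anchors the spectrum at 555 nm", {
  s <- spectrum(360:830, seq_along(360:830), "relative")
  a <- normalize_at(s)
  expect_equal(a$values[a$wavelength_nm == 555], 1)
  expect_equal(a$values, s$values / s$values[s$wavelength_nm == 555])
  expect_equal(normalize_at(flat_spectrum(7))$values, rep(1, 471))
  z_vals <- rep(1, 471); z_vals[555 - 360 + 1] <- 0
  z <- spectrum(360:830, z_vals, "relative")
  expect_error(normalize_at(z), "not positive")
  expect_error(normalize_at(s, 555.5), "not a grid point")
})
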