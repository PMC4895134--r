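make_lib <- function(grid = seq(300, 800, by = 2)) {
  dk <- function(t, temp, level)
    dark_frame(t, temp, spectrum(grid, rep(level, length(grid)), "counts"))
  dark_library(list(dk(1, 10, 100), dk(1, 30, 200),
                    dk(10, 10, 400), dk(10, 30, 800)))
}

test_that("lookup_dark interpolates in temperature and clamps", {
  lib <- make_lib()
  expect_true(all(lookup_dark(lib, 1, 10)$values == 100))
  expect_true(all(lookup_dark(lib, 1, 20)$values == 150))   # midpoint
  expect_true(all(lookup_dark(lib, 10, 50)$values == 800))  # clamp above
  expect_true(all(lookup_dark(lib, 10, 0)$values == 400))   # clamp below
  expect_error(lookup_dark(lib, 3, 20), "no dark frames")
})

test_that("wavelength shifts are recovered from synthetic line frames", {
  lines <- skyspec_reference_lines()
  make_lamp <- function(shift, grid = seq(380, 800, by = 0.3)) {
    v <- 10 + 20000 * Reduce(`+`, lapply(lines, function(l)
      exp(-(grid + shift - l)^2 / (2 * 1.2^2))))
    spectrum(grid, v, "counts")
  }
  est <- estimate_wavelength_shift(make_lamp(-0.8), lines)
  expect_equal(est$shift_nm, -0.8, tolerance = 0.05)
  expect_lt(est$sd_nm, 0.05)
  expect_equal(est$n_matched, length(lines))
  est0 <- estimate_wavelength_shift(make_lamp(0), lines)
  expect_equal(est0$shift_nm, 0, tolerance = 0.05)
  # injected shifts across [-2, 2] nm recovered within the grid spacing
  set.seed(1)
  shifts <- stats::runif(25, -2, 2)
  for (sft in shifts) {
    lamp <- make_lamp(sft)
    lamp$values <- pmax(lamp$values + stats::rnorm(length(lamp$values), 0, 5), 0)
    expect_lt(abs(estimate_wavelength_shift(lamp, lines)$shift_nm - sft), 0.3)
  }
  expect_error(
    estimate_wavelength_shift(flat_spectrum(1, 380, 800), lines),
    "fewer than 2 peaks")
})

test_that("correction factors are the reference/measured ratio", {
  wl <- 380:780
  ref <- spectrum(wl, 2 + sin(wl / 40), "relative")
  expect_true(all(derive_correction_factors(ref, ref)$factors == 1))
  half <- spectrum(wl, ref$values / 2, "relative")
  expect_equal(derive_correction_factors(half, ref)$factors,
               rep(2, length(wl)))
  f <- 1 + 0.5 * cos(wl / 60)                      # known factor curve
  meas <- spectrum(wl, ref$values / f, "relative")
  expect_equal(derive_correction_factors(meas, ref)$factors, f,
               tolerance = 1e-12)
  expect_error(derive_correction_factors(
    spectrum(300:350, rep(1, 51), "relative"), ref), "overlap")
})

test_that("splice_corrections rescales and ramps across the transitions", {
  wl_s <- 280:440; wl_m <- 360:800; wl_l <- 720:840
  base <- function(wl) 1e-10 * (1 + ((wl - 560) / 400)^2)
  s_cf <- correction_factors(wl_s, base(wl_s))
  m_cf <- correction_factors(wl_m, base(wl_m))
  l_cf <- correction_factors(wl_l, base(wl_l))

  same <- splice_corrections(s_cf, m_cf, l_cf)
  expect_equal(same$scale_short, 1, tolerance = 1e-12)
  expect_equal(same$scale_long, 1, tolerance = 1e-12)
  expect_equal(same$cf$factors,
               base(same$cf$wavelength_nm), tolerance = 1e-12)

  tripled <- correction_factors(wl_l, 3 * base(wl_l))
  sp <- splice_corrections(s_cf, m_cf, tripled)
  expect_equal(sp$scale_long, 1 / 3, tolerance = 1e-12)
  overlap <- sp$cf$wavelength_nm >= 720 & sp$cf$wavelength_nm <= 800
  expect_equal(sp$cf$factors[overlap], base(sp$cf$wavelength_nm[overlap]),
               tolerance = 1e-12)

  # equal weighting at the transition wavelength itself
  shifted <- correction_factors(wl_s, base(wl_s) + 2e-11)
  sp2 <- splice_corrections(shifted, m_cf, l_cf)
  at400 <- sp2$cf$factors[sp2$cf$wavelength_nm == 400]
  lhs <- sp2$scale_short * (base(400) + 2e-11)
  expect_equal(at400, 0.5 * lhs + 0.5 * base(400), tolerance = 1e-12)

  # blended output is continuous across the ramp edges
  expect_true(all(abs(diff(sp2$cf$factors)) < 5e-12))
  expect_error(splice_corrections(
    correction_factors(280:390, base(280:390)), m_cf, l_cf),
    "not covered")
})

test_that("window_snr separates smooth structure from noise", {
  wl <- 360:830
  smooth <- window_snr(spectrum(wl, (wl / 100)^2, "relative"))
  interior <- smooth$wavelength_nm > 380 & smooth$wavelength_nm < 810
  expect_true(all(smooth$abs_corr[interior] > 0.95, na.rm = TRUE))
  # constant spectrum: zero variance in every window, flagged
  expect_true(all(is.na(window_snr(flat_spectrum(2))$abs_corr)))
  # independent noise: near zero on average across seeds
  mean_abs <- vapply(1:200, function(seed) {
    set.seed(seed)
    mean(window_snr(spectrum(500:580, stats::rnorm(81), "counts"))$abs_corr,
         na.rm = TRUE)
  }, 0)
  expect_lt(mean(mean_abs), 0.35)
  expect_lt(mean(mean_abs), min(smooth$abs_corr[interior]))
})

test_that("process_raw applies the documented correction chain", {
  grid <- seq(300, 800, by = 2)
  lib <- make_lib(grid)
  cf <- correction_factors(360:700, rep(2e-3, 341))
  # counts built so that post-correction radiance is exactly 1 everywhere
  rate <- 1 / 2e-3        # count rate whose corrected radiance is exactly 1
  counts <- spectrum(grid, rep(rate * 10 + 400, length(grid)), "counts")
  out <- process_raw(raw_frame(counts, 10, 10), lib, 0, cf)
  expect_equal(out$values, rep(pi, length(out$values)), tolerance = 1e-12)
  expect_identical(out$units, "irradiance_W_m2_nm")

  # a frame equal to its dark calibrates to zero
  dark_only <- raw_frame(spectrum(grid, rep(400, length(grid)), "counts"),
                         10, 10)
  expect_true(all(process_raw(dark_only, lib, 0, cf)$values == 0))

  # homogeneous of degree 1 in (counts - dark)
  doubled <- raw_frame(spectrum(grid, rep(2 * rate * 10 + 400, length(grid)), "counts"), 10, 10)
  expect_equal(process_raw(doubled, lib, 0, cf)$values, 2 * out$values,
               tolerance = 1e-12)

  # the wavelength shift moves the grid before resampling
  ramp <- raw_frame(spectrum(grid, grid * 10 + 400, "counts"), 10, 10)
  shifted <- process_raw(ramp, lib, 5, cf)
  expect_equal(shifted$values,
               (shifted$wavelength_nm - 5) * 2e-3 * pi, tolerance = 1e-9)
})

test_that("qc_filter rejects saturated and dark-equal frames with reasons", {
  grid <- seq(300, 800, by = 2)
  lib <- make_lib(grid)
  cf <- correction_factors(360:700, rep(2e-3, 341))
  ok <- function(level) raw_frame(
    spectrum(grid, rep(level, length(grid)), "counts"), 10, 10)
  sat_counts <- rep(1000, length(grid)); sat_counts[100] <- 65535
  frames <- list(a = ok(5000), b = ok(1500),
                 sat = raw_frame(spectrum(grid, sat_counts, "counts"), 10, 10),
                 dark = ok(400), c = ok(800))
  res <- qc_filter(frames, lib, 0, cf)
  expect_named(res$kept, c("a", "b", "c"))
  expect_setequal(res$rejected$id, c("sat", "dark"))
  expect_setequal(res$rejected$reason,
                  c("saturated", "all_zero_after_dark_subtraction"))
  # one slightly negative post-dark value is clamped, frame kept
  neg <- rep(1500, length(grid)); neg[50] <- 350
  res2 <- qc_filter(list(n = raw_frame(spectrum(grid, neg, "counts"), 10, 10)),
                    lib, 0, cf)
  expect_length(res2$kept, 1)
  expect_true(all(res2$kept$n$values >= 0))
  empty <- qc_filter(list(), lib, 0, cf)
  expect_length(empty$kept, 0)
  expect_equal(nrow(empty$rejected), 0)
})
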