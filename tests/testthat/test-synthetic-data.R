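test_that("moon brightness anchors and monotonicity", {
  expect_equal(moon_brightness(1), 1)
  expect_equal(moon_brightness(0), 0)
  expect_equal(moon_brightness(0.3), 0.0329, tolerance = 1e-12)
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(moon_brightness(f)) > 0))
  expect_error(moon_brightness(1.2), "within")
})

test_that("true spectra combine daylight, night floor and moonlight", {
  cfg <- sky_sim_config(seed = 2, noise = FALSE)
  vis <- wavelength_band(400, 800, "VIS")

  # high sun: CIE-like daylight, negligible ozone dip, excellent CIE fit
  day <- true_spectrum(60, -30, 0, "rural", cfg)
  f <- fit_spectrum(load_cie_basis(),
                    resample_1nm(day, 360, 830))
  expect_gt(f$r_squared, 0.99)

  # deep night: the sigmoid term is negligible, the floor dominates
  night <- true_spectrum(-30, -30, 0, "rural", cfg)
  floor_vis <- band_irradiance(night, vis)
  expect_equal(log10(floor_vis),
               cfg$intensity$night_floor_log10[["rural"]], tolerance = 1e-6)

  # city floor is 100x the rural floor over VIS
  city <- true_spectrum(-30, -30, 0, "city", cfg)
  expect_equal(band_irradiance(city, vis) / floor_vis, 100,
               tolerance = 1e-6)

  # moon below the horizon contributes exactly zero
  no_moon <- true_spectrum(-30, -5, 1, "rural", cfg)
  expect_identical(no_moon$values, night$values)
  # a full moon overwhelms the rural night floor
  full <- true_spectrum(-30, 45, 1, "rural", cfg)
  expect_gt(band_irradiance(full, vis) / floor_vis, 50)
  # and a quarter moon contributes far less than a full moon
  quarter <- true_spectrum(-30, 45, 0.3, "rural", cfg)
  expect_equal((band_irradiance(quarter, vis) - floor_vis) /
                 (band_irradiance(full, vis) - floor_vis), 0.0329,
               tolerance = 1e-6)
})

test_that("log VIS intensity is non-decreasing in solar elevation", {
  cfg <- sky_sim_config(seed = 2, noise = FALSE)
  vis <- wavelength_band(400, 800, "VIS")
  th <- seq(-18, 20, by = 1)
  for (loc in c("rural", "city")) {
    iv <- vapply(th, function(t)
      band_irradiance(true_spectrum(t, -30, 0, loc, cfg), vis), 0)
    expect_true(all(diff(log10(iv)) > -1e-9), info = loc)
  }
  # eight-decade span between midday and rural night
  top <- band_irradiance(true_spectrum(60, -30, 0, "rural", cfg), vis)
  bottom <- band_irradiance(true_spectrum(-30, -30, 0, "rural", cfg), vis)
  expect_gt(log10(top / bottom), 7.5)
})

test_that("the twilight blue shift peaks at the configured elevation", {
  cfg <- sky_sim_config(seed = 2, noise = FALSE)
  th <- seq(-19, -1, by = 2)
  x_of <- function(cfg) vapply(th, function(t) {
    s <- resample_1nm(true_spectrum(t, -30, 0, "rural", cfg), 360, 830)
    xyz <- xyz_from_spectrum(s)
    xy_from_xyz(xyz["X"], xyz["Y"], xyz["Z"])$x
  }, 0)
  x <- x_of(cfg)
  expect_true(th[which.min(x)] %in% c(-13, -11))
  # disabling the ozone band removes the dip: x becomes monotone-ish,
  # with no interior minimum more than marginally below both ends
  x0 <- x_of(sky_sim_config(seed = 2, noise = FALSE,
                            chappuis = list(tau_max = 0)))
  expect_gt(min(x0), min(x) + 0.02)
})

test_that("instrument_forward inverts through process_raw without noise", {
  cfg <- sky_sim_config(seed = 9, noise = FALSE)
  cf <- instrument_response("A", cfg)
  # truth chosen so the pixel-sampled count rate is exactly linear, making
  # the 1-nm resampling lossless
  wl <- seq(170, 880, by = 0.005)
  cf_pl <- stats::approx(cf$wavelength_nm, cf$factors, wl, rule = 2)$y
  truth <- spectrum(wl, (100 + 2 * wl) * pi * cf_pl, "irradiance_W_m2_nm")
  fr <- instrument_forward(truth, "A", 10, 25, cfg)
  lib <- build_dark_library("A", cfg)
  out <- process_raw(fr, lib, cfg$instruments$A$shift_nm, cf)
  want <- (100 + 2 * out$wavelength_nm) * pi *
    cf$factors[match(out$wavelength_nm, cf$wavelength_nm)]
  expect_lt(max(abs(out$values - want) / want), 1e-9)

  # doubling the truth doubles the pre-clip signal counts
  fr2 <- instrument_forward(spectrum(wl, 2 * truth$values,
                                     "irradiance_W_m2_nm"), "A", 10, 25, cfg)
  dark <- lookup_dark(lib, 10, 25)
  expect_equal(fr2$counts$values - dark$values,
               2 * (fr$counts$values - dark$values), tolerance = 1e-9)

  # an over-bright source saturates and is rejected by QC
  bright <- spectrum(wl, 1e4 * truth$values, "irradiance_W_m2_nm")
  frb <- instrument_forward(bright, "A", 10, 25, cfg)
  expect_true(any(frb$counts$values >= frb$saturation_level))
  qc <- qc_filter(list(b = frb), lib, cfg$instruments$A$shift_nm, cf)
  expect_equal(qc$rejected$reason, "saturated")
})

test_that("campaigns are deterministic, complete and well-formed", {
  cfg <- sky_sim_config(seed = 5, acquisition = list(sample_every_s = 600))
  c1 <- generate_campaign(cfg)
  c2 <- generate_campaign(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$frames, c2$frames)
  expect_identical(c1$ground_truth, c2$ground_truth)

  # every illumination regime is represented at both locations
  for (loc in c("rural", "city")) {
    th <- c1$records$solar_elevation_deg[c1$records$location_id == loc]
    expect_gt(max(th), 15); expect_lt(min(th), -25)
    expect_setequal(as.character(unique(classify_regime(th))),
                    c("day", "civil", "nautical", "astronomical", "night"))
  }
  # dawn and dusk sequences both occur
  expect_setequal(unique(c1$records$sequence), c("dawn", "dusk"))
  # the ephemeris table reproduces each record's geometry at its timestamp
  rur <- c1$records[c1$records$location_id == "rural", ]
  look <- interpolate_ephemeris(c1$ephemeris$rural, rur$timestamp)
  expect_equal(look$solar_elevation_deg, rur$solar_elevation_deg,
               tolerance = 1e-9)
  expect_equal(look$fraction_illuminated, rur$fraction_illuminated,
               tolerance = 1e-9)
  # truth spectra are reproducible from the record geometry alone
  id <- rur$record_id[40]
  i <- match(id, c1$records$record_id)
  redo <- true_spectrum(c1$records$solar_elevation_deg[i],
                        c1$records$lunar_elevation_deg[i],
                        c1$records$fraction_illuminated[i], "rural",
                        c1$config)
  expect_identical(redo$values, c1$truth[[id]]$values)
})
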