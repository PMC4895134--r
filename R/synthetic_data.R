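#' Configuration of the synthetic sky-spectrum campaign
#'
#' Builds the full parameter set of the two-location observation simulator:
#' an intensity curve spanning eight decades between midday and rural night,
#' CIE-daylight spectral shape with solar-elevation-dependent CCT, ozone
#' (Chappuis-band) attenuation peaking in nautical/astronomical twilight,
#' location-specific night floors (airglow-dominated rural, sodium-lamp
#' city at one hundred times the rural level), additive moonlight, and a
#' two-instrument acquisition model with dark noise, read noise, shot noise
#' and saturation.
#'
#' Defaults encode the emulated study conditions; override individual entries
#' via `...` using the same nested names (e.g.
#' `sky_sim_config(chappuis = list(tau_max = 0))`).
#'
#' @param seed Integer RNG seed; a fixed seed makes [generate_campaign()]
#'   byte-reproducible.
#' @param noise Logical; disable to make the instrument model deterministic
#'   (dark offset still applied, no shot/read noise).
#' @param ... Named overrides merged into the default configuration.
#' @return A `sky_sim_config` list.
#' @export
sky_sim_config <- function(seed = 1L, noise = TRUE, ...) {
  cfg <- list(
    seed = as.integer(seed),
    noise = isTRUE(noise),
    wavelength_nm = 280:1025,
    intensity = list(
      day_log10 = 2.6,                      # log10 W m^-2 over VIS at midday
      night_floor_log10 = c(rural = -5.4, city = -3.4),
      center_deg = 0, slope_dex_per_deg = 0.58, smooth_deg = 2),
    daylight_cct = list(base_K = 6500, twilight_gain_K_per_deg = 180,
                        min_K = 4000, max_K = 25000),
    chappuis = list(center_nm = 600, width_nm = 50, tau_max = 3,
                    peak_elev_deg = -12, elev_width_deg = 4),
    rural_night = list(line_center_nm = 558, line_sigma_nm = 2.5,
                       line_peak_rel = 8,
                       line2_center_nm = 630, line2_sigma_nm = 2.5,
                       line2_peak_rel = 1.5),
    city_night = list(band_center_nm = 589, band_sigma_nm = 25,
                      band_peak_rel = 1,
                      nir_line_nm = 819, nir_line_sigma_nm = 2.5,
                      nir_line_peak_rel = 3,
                      base_rel = 0.15),
    moonlight = list(gamma = log(0.0329) / log(0.3),
                     full_moon_vis_W_m2 = 10^-2.9, cct_K = 4500),
    instruments = list(
      A = list(range_nm = c(180, 875), n_pixels = 1044, shift_nm = -0.79,
               cf_base = 1e-11, read_noise_sd = 15,
               resample_range_nm = c(280, 840)),
      B = list(range_nm = c(340, 1025), n_pixels = 1054, shift_nm = -0.98,
               cf_base = 1e-8, read_noise_sd = 15,
               resample_range_nm = c(360, 840))),
    dark = list(offset_counts = 100, rate_counts_per_s = 2,
                temp_coef_per_C = 0.04, library_temps_C = c(5, 15, 25, 35)),
    acquisition = list(
      ladder_s = c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 60),
      target_fraction = 0.85, saturation_level = 65535,
      instrument_switch_deg = -6, sample_every_s = 60),
    campaign = list(
      elev_mid_deg = 5, elev_amp_deg = 40, window_deg = c(-26, 16),
      moon_mid_deg = -10, moon_amp_deg = 50,
      start_utc = "2016-05-26 12:00:00",
      sessions = list(
        rural = list(list(fraction = 0.05, moon_transit_h = 16),
                     list(fraction = 0.22, moon_transit_h = 14)),
        city = list(list(fraction = 0.55, moon_transit_h = 14),
                    list(fraction = 0.85, moon_transit_h = 13.5)))))
  override <- list(...)
  for (nm in names(override)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(override[[nm]]))
      utils::modifyList(cfg[[nm]], override[[nm]]) else override[[nm]]
  }
  if (any(unlist(cfg$intensity$night_floor_log10) >= cfg$intensity$day_log10))
    stop("night floor must lie below the day level", call. = FALSE)
  structure(cfg, class = "sky_sim_config")
}

#' Relative lunar brightness as a function of illuminated fraction
#'
#' A power law `b(f) = f^gamma` anchored so that the full moon has brightness
#' 1 and a fraction of 0.3 has brightness 0.0329 (3.29% of full moon), which
#' fixes `gamma = log(0.0329)/log(0.3)`. Monotone increasing with `b(0) = 0`.
#'
#' @param fraction Fraction of the moon illuminated, in [0, 1] (vectorised).
#' @param gamma Power-law exponent; default anchors the two printed values.
#' @return Relative brightness in [0, 1].
#' @export
moon_brightness <- function(fraction, gamma = log(0.0329) / log(0.3)) {
  if (any(fraction < 0 | fraction > 1))
    stop("fraction illuminated must lie within [0, 1]", call. = FALSE)
  fraction^gamma
}

gauss_peak <- function(wl, center, sigma) exp(-(wl - center)^2 / (2 * sigma^2))

# VIS (400-800 nm) trapezoidal integral on an arbitrary grid
vis_integral <- function(wl, v) {
  band_irradiance(spectrum(wl, pmax(v, 0), "irradiance_W_m2_nm"),
                  wavelength_band(400, 800, "VIS"))
}

# CIE daylight shape extended onto the master grid: zero below the component
# tables' support, exponential taper above 830 nm, negatives clamped
daylight_shape <- function(cct_K, wl) {
  d <- cie_daylight_spectrum(cct_K, 300, 830)
  v <- rep(0, length(wl))
  inside <- wl >= 300 & wl <= 830
  v[inside] <- stats::approx(d$wavelength_nm, d$values, wl[inside])$y
  above <- wl > 830
  v[above] <- d$values[length(d$values)] * exp(-(wl[above] - 830) / 150)
  pmax(v, 0)
}

# location night-floor template, normalised to unit VIS integral
night_template <- function(location, cfg) {
  wl <- cfg$wavelength_nm
  if (location == "rural") {
    rn <- cfg$rural_night
    cont <- 1 + 0.25 * sin(2 * pi * wl / 70 + 0.7) +
      0.15 * sin(2 * pi * wl / 23 + 2.1)
    cont <- pmax(cont, 0.2) * (1 + 0.5 / (1 + exp(-(wl - 720) / 30)))
    v <- cont +
      rn$line_peak_rel * gauss_peak(wl, rn$line_center_nm, rn$line_sigma_nm) +
      rn$line2_peak_rel * gauss_peak(wl, rn$line2_center_nm, rn$line2_sigma_nm)
  } else {
    cn <- cfg$city_night
    v <- cn$base_rel +
      cn$band_peak_rel * gauss_peak(wl, cn$band_center_nm, cn$band_sigma_nm) +
      2.0 * gauss_peak(wl, 569, 2) +
      6.0 * gauss_peak(wl, 589, 3) +
      2.5 * gauss_peak(wl, 595, 2) +
      2.0 * gauss_peak(wl, 615, 3) +
      0.8 * gauss_peak(wl, 436, 2) +
      0.8 * gauss_peak(wl, 546, 2) +
      cn$nir_line_peak_rel * gauss_peak(wl, cn$nir_line_nm, cn$nir_line_sigma_nm)
  }
  v / vis_integral(wl, v)
}

# VIS-integrated daylight-term intensity (W m^-2): softplus ramp in log10,
# linear decline below the horizon at `slope_dex_per_deg`, flat day plateau
intensity_daylight_vis <- function(theta_s, cfg) {
  p <- cfg$intensity
  z <- -(theta_s - p$center_deg) / p$smooth_deg
  softplus <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  10^(p$day_log10 - p$slope_dex_per_deg * p$smooth_deg * softplus)
}

cct_of_elevation <- function(theta_s, cfg) {
  p <- cfg$daylight_cct
  pmin(pmax(p$base_K + p$twilight_gain_K_per_deg * pmax(-theta_s, 0),
            p$min_K), p$max_K)
}

#' True downwelling irradiance spectrum under the simulator's sky model
#'
#' The noise-free scene spectrum at a given solar/lunar geometry: a CIE
#' daylight term at the elevation-dependent CCT, scaled by the intensity
#' curve and attenuated by the Chappuis ozone band (optical depth peaking by
#' default at -12 degrees), plus the location's night-floor template and an
#' additive moonlight term scaled by lunar fraction and elevation.
#'
#' @param theta_s Solar elevation, degrees in [-90, 90].
#' @param lunar_elev_deg Lunar elevation, degrees.
#' @param fraction Fraction of the moon illuminated, in [0, 1].
#' @param location `"rural"` or `"city"`.
#' @param cfg A `sky_sim_config`.
#' @return A `spectrum` (units irradiance) on the master grid.
#' @export
true_spectrum <- function(theta_s, lunar_elev_deg, fraction, location, cfg) {
  stopifnot(inherits(cfg, "sky_sim_config"),
            location %in% c("rural", "city"))
  if (abs(theta_s) > 90)
    stop("solar elevation outside [-90, 90]", call. = FALSE)
  wl <- cfg$wavelength_nm

  shape <- daylight_shape(cct_of_elevation(theta_s, cfg), wl)
  shape <- shape / vis_integral(wl, shape)
  ch <- cfg$chappuis
  tau <- ch$tau_max *
    exp(-(theta_s - ch$peak_elev_deg)^2 / (2 * ch$elev_width_deg^2))
  atten <- exp(-tau * gauss_peak(wl, ch$center_nm, ch$width_nm))
  day <- intensity_daylight_vis(theta_s, cfg) * shape * atten

  floor_level <- 10^cfg$intensity$night_floor_log10[[location]]
  floor <- floor_level * night_template(location, cfg)

  moon <- 0
  if (lunar_elev_deg > 0 && fraction > 0) {
    ms <- daylight_shape(cfg$moonlight$cct_K, wl)
    ms <- ms / vis_integral(wl, ms)
    moon <- cfg$moonlight$full_moon_vis_W_m2 *
      moon_brightness(fraction, cfg$moonlight$gamma) *
      sin(lunar_elev_deg * pi / 180) * ms
  }
  spectrum(wl, day + floor + moon, "irradiance_W_m2_nm")
}

# non-uniform factory pixel grid with a mild quadratic chirp
pixel_grid <- function(icfg) {
  u <- seq(0, 1, length.out = icfg$n_pixels)
  icfg$range_nm[1] + diff(icfg$range_nm) * (u + 0.03 * u * (1 - u))
}

# tabulated instrument response: correction factors on the 1-nm resample
# grid; the forward model interpolates this table linearly, so the table is
# the exact inverse of the simulated sensitivity
instrument_cf <- function(icfg) {
  wl <- seq(icfg$resample_range_nm[1], icfg$resample_range_nm[2], by = 1)
  correction_factors(wl, icfg$cf_base * exp(((wl - 560) / 300)^2))
}

#' Tabulated instrument response of a simulated spectrometer
#'
#' The correction-factor table (counts-per-second to radiance) on the
#' instrument's 1-nm resample grid. The forward model treats this table,
#' linearly interpolated, as the exact instrument sensitivity, so calibrating
#' with it inverts [instrument_forward()] up to noise.
#'
#' @param instrument `"A"` or `"B"`.
#' @param cfg A `sky_sim_config`.
#' @return A `correction_factors` object.
#' @export
instrument_response <- function(instrument, cfg) {
  instrument_cf(cfg$instruments[[instrument]])
}

cf_at <- function(cf, wl) {
  stats::approx(cf$wavelength_nm, cf$factors, xout = wl, rule = 2)$y
}

# mean dark counts: affine in integration time, exponential in temperature,
# with a deterministic per-wavelength fixed pattern
dark_mean_counts <- function(wl, t_int, temp_C, cfg) {
  fp <- 1 + 0.15 * sin(wl / 9.1) + 0.08 * sin(wl / 2.3)
  cfg$dark$offset_counts + cfg$dark$rate_counts_per_s * fp * t_int *
    exp(cfg$dark$temp_coef_per_C * (temp_C - 20))
}

#' Build a dark library for one instrument
#'
#' Mean dark spectra over the full integration-time ladder crossed with the
#' configured library temperatures, on the instrument's factory pixel grid.
#'
#' @param instrument `"A"` or `"B"`.
#' @param cfg A `sky_sim_config`.
#' @return A `dark_library`.
#' @export
build_dark_library <- function(instrument, cfg) {
  icfg <- cfg$instruments[[instrument]]
  g <- pixel_grid(icfg)
  frames <- list()
  for (t_int in cfg$acquisition$ladder_s)
    for (temp in cfg$dark$library_temps_C)
      frames[[length(frames) + 1L]] <- dark_frame(
        t_int, temp,
        spectrum(g, dark_mean_counts(g, t_int, temp, cfg), "counts"))
  dark_library(frames)
}

#' Simulate a raw frame from a truth spectrum
#'
#' The instrument forward model: the truth spectrum is sampled at the factory
#' pixel positions offset by the instrument's (injected) wavelength-
#' calibration shift, divided by pi and by the tabulated response
#' (interpolated linearly), scaled by the integration time, and combined with
#' the mean dark spectrum. With noise enabled, Poisson shot noise on the
#' signal counts and Gaussian read noise are added. Counts are clipped to
#' [0, saturation].
#'
#' @param truth A `spectrum` (irradiance) covering the instrument range.
#' @param instrument `"A"` or `"B"`.
#' @param t_int Integration time in seconds.
#' @param temp_C Board temperature.
#' @param cfg A `sky_sim_config`.
#' @param noise Logical; defaults to the config's `noise` flag.
#' @return A `raw_frame`.
#' @export
instrument_forward <- function(truth, instrument, t_int, temp_C, cfg,
                               noise = cfg$noise) {
  icfg <- cfg$instruments[[instrument]]
  g <- pixel_grid(icfg)
  lam <- g + icfg$shift_nm
  tv <- stats::approx(truth$wavelength_nm, truth$values, xout = lam,
                      rule = 2)$y
  signal <- tv / (pi * cf_at(instrument_cf(icfg), lam)) * t_int
  signal <- pmax(signal, 0)
  if (noise) signal <- stats::rpois(length(signal), signal) +
    stats::rnorm(length(signal), 0, icfg$read_noise_sd)
  counts <- signal + dark_mean_counts(g, t_int, temp_C, cfg)
  counts <- pmin(pmax(counts, 0), cfg$acquisition$saturation_level)
  raw_frame(spectrum(g, counts, "counts"), t_int, temp_C,
            instrument_id = instrument,
            saturation_level = cfg$acquisition$saturation_level)
}

# largest ladder integration time whose predicted peak counts stay below the
# target fraction of saturation (falls back to the shortest time)
auto_integration_time <- function(truth, instrument, temp_C, cfg) {
  icfg <- cfg$instruments[[instrument]]
  g <- pixel_grid(icfg)
  lam <- g + icfg$shift_nm
  tv <- stats::approx(truth$wavelength_nm, truth$values, xout = lam,
                      rule = 2)$y
  peak_rate <- max(tv / (pi * cf_at(instrument_cf(icfg), lam)))
  limit <- cfg$acquisition$target_fraction * cfg$acquisition$saturation_level
  ok <- vapply(cfg$acquisition$ladder_s, function(t) {
    peak_rate * t + max(dark_mean_counts(g, t, temp_C, cfg)) <= limit
  }, TRUE)
  if (any(ok)) max(cfg$acquisition$ladder_s[ok]) else
    min(cfg$acquisition$ladder_s)
}

# Hg + Ar calibration-lamp frames on the instrument grid, with the injected
# shift, for wavelength-calibration recovery
make_line_frames <- function(instrument, cfg, noise = cfg$noise) {
  icfg <- cfg$instruments[[instrument]]
  g <- pixel_grid(icfg)
  lam <- g + icfg$shift_nm
  lines <- skyspec_reference_lines()
  v <- 50 + 30000 * Reduce(`+`, lapply(lines, function(l)
    gauss_peak(lam, l, 1.2)))
  if (noise) v <- v + stats::rnorm(length(v), 0, icfg$read_noise_sd)
  spectrum(g, pmax(v, 0), "counts")
}

#' Reference emission lines for wavelength calibration
#'
#' The mercury (404.7, 435.8, 546.1, 579 nm) and argon (696.5, 706.7, 727.3,
#' 738.4, 763.5 nm) lamp lines used to validate the factory wavelength
#' calibration.
#'
#' @return Sorted numeric vector of line positions (nm).
#' @export
skyspec_reference_lines <- function() {
  c(404.7, 435.8, 546.1, 579, 696.5, 706.7, 727.3, 738.4, 763.5)
}

#' Generate a complete synthetic observation campaign
#'
#' Simulates per-minute dusk and dawn acquisition sequences at both locations
#' (sinusoidal solar track sampled while the solar elevation is inside the
#' acquisition window), assigns each record to the daylight ('B', used at
#' `theta_s` above the switch elevation) or high-sensitivity ('A') instrument
#' with an automatic integration-time ladder, and produces: the record
#' metadata, raw frames, noise-free truth spectra, per-instrument dark
#' libraries, response tables and calibration-lamp frames, per-location
#' ephemeris tables, and a ground-truth ledger. Deterministic for a fixed
#' config seed.
#'
#' @param cfg A `sky_sim_config`.
#' @return A `sky_campaign` list with elements `records`, `frames`, `truth`,
#'   `dark_libs`, `cf`, `shifts`, `line_frames`, `ephemeris`, `ground_truth`
#'   and `config`.
#' @export
generate_campaign <- function(cfg = sky_sim_config()) {
  stopifnot(inherits(cfg, "sky_sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  cc <- cfg$campaign
  t0 <- as.POSIXct(cc$start_utc, tz = "UTC")       # solar noon, session 1
  omega <- 2 * pi / 86400
  records <- list(); frames <- list(); truth <- list()
  eph <- list()

  for (loc in names(cc$sessions)) {
    loc_rows <- list()
    for (si in seq_along(cc$sessions[[loc]])) {
      ses <- cc$sessions[[loc]][[si]]
      noon <- t0 + (si - 1) * 86400 + (loc == "city") * 2 * 86400
      tt <- noon + seq(0, 86400 - cfg$acquisition$sample_every_s,
                       by = cfg$acquisition$sample_every_s)
      dt <- as.numeric(tt - noon, units = "secs")
      theta <- cc$elev_mid_deg + cc$elev_amp_deg * cos(omega * dt)
      keep <- theta >= cc$window_deg[1] & theta <= cc$window_deg[2]
      moon_el <- cc$moon_mid_deg + cc$moon_amp_deg *
        cos(omega * (dt - (ses$moon_transit_h - 12) * 3600))
      temp <- 18 + 6 * sin(omega * dt - 2) + si
      loc_rows[[si]] <- data.frame(
        timestamp = tt[keep], session_id = si,
        solar_elevation_deg = theta[keep],
        lunar_elevation_deg = moon_el[keep],
        fraction_illuminated = ses$fraction,
        board_temp_C = temp[keep])
    }
    df <- do.call(rbind, loc_rows)
    df$location_id <- loc
    eph[[loc]] <- ephemeris_table(df$timestamp, df$solar_elevation_deg,
                                  df$lunar_elevation_deg,
                                  df$fraction_illuminated)
    records[[loc]] <- df
  }
  rec <- do.call(rbind, records)
  rec$instrument_id <- ifelse(
    rec$solar_elevation_deg >= cfg$acquisition$instrument_switch_deg, "B", "A")
  rec$record_id <- sprintf("%s_s%d_%04d", rec$location_id, rec$session_id,
                           stats::ave(seq_len(nrow(rec)),
                                      paste(rec$location_id, rec$session_id),
                                      FUN = seq_along))
  rownames(rec) <- NULL

  rec$integration_time_s <- NA_real_
  for (i in seq_len(nrow(rec))) {
    ts <- true_spectrum(rec$solar_elevation_deg[i],
                        rec$lunar_elevation_deg[i],
                        rec$fraction_illuminated[i],
                        rec$location_id[i], cfg)
    t_int <- auto_integration_time(ts, rec$instrument_id[i],
                                   rec$board_temp_C[i], cfg)
    rec$integration_time_s[i] <- t_int
    truth[[rec$record_id[i]]] <- ts
    frames[[rec$record_id[i]]] <- instrument_forward(
      ts, rec$instrument_id[i], t_int, rec$board_temp_C[i], cfg)
  }
  rec <- assign_sequence(rec)

  shifts <- vapply(cfg$instruments, `[[`, 0, "shift_nm")
  structure(list(
    records = rec, frames = frames, truth = truth,
    dark_libs = list(A = build_dark_library("A", cfg),
                     B = build_dark_library("B", cfg)),
    cf = list(A = instrument_cf(cfg$instruments$A),
              B = instrument_cf(cfg$instruments$B)),
    shifts = shifts,
    line_frames = list(A = make_line_frames("A", cfg),
                       B = make_line_frames("B", cfg)),
    ephemeris = eph,
    ground_truth = list(
      seed = cfg$seed,
      shifts_nm = as.list(shifts),
      night_floor_log10 = as.list(cfg$intensity$night_floor_log10),
      airglow_line_nm = cfg$rural_night$line_center_nm,
      sodium_band_nm = c(570, 615),
      sodium_nir_line_nm = cfg$city_night$nir_line_nm,
      chappuis_peak_elev_deg = cfg$chappuis$peak_elev_deg,
      moon_gamma = cfg$moonlight$gamma,
      dark = cfg$dark),
    config = cfg), class = "sky_campaign")
}

#' @export
print.sky_campaign <- function(x, ...) {
  cat(sprintf("<sky_campaign> %d records (%s), seed %d\n", nrow(x$records),
              paste(sprintf("%s: %d", names(table(x$records$location_id)),
                            table(x$records$location_id)), collapse = ", "),
              x$config$seed))
  invisible(x)
}
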