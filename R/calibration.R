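#' Dark frames and dark libraries
#'
#' A dark frame is a no-light exposure characterising detector offset as a
#' function of integration time and board temperature. A dark library collects
#' frames over a grid of integration times and temperatures; per-wavelength
#' linear interpolation in temperature is used at lookup time (integration
#' times are matched exactly).
#'
#' @param integration_time_s Integration time in seconds (> 0).
#' @param board_temp_C Board temperature in degrees Celsius.
#' @param dark_counts A `spectrum` with units `"counts"`, values >= 0.
#' @return `dark_frame()` returns a `dark_frame`; `dark_library()` a
#'   `dark_library` wrapping a list of frames.
#' @export
dark_frame <- function(integration_time_s, board_temp_C, dark_counts) {
  stopifnot(inherits(dark_counts, "spectrum"), integration_time_s > 0)
  if (dark_counts$units != "counts")
    stop("dark frames must be in counts", call. = FALSE)
  if (any(dark_counts$values < 0))
    stop("dark counts must be non-negative", call. = FALSE)
  structure(list(integration_time_s = integration_time_s,
                 board_temp_C = board_temp_C,
                 dark_counts = dark_counts),
            class = "dark_frame")
}

#' @param frames List of `dark_frame` objects; every integration time must be
#'   represented at two or more temperatures so that interpolation is defined.
#' @rdname dark_frame
#' @export
dark_library <- function(frames) {
  stopifnot(length(frames) > 0, all(vapply(frames, inherits, TRUE, "dark_frame")))
  tint <- vapply(frames, `[[`, 0, "integration_time_s")
  for (t in unique(tint)) {
    temps <- vapply(frames[tint == t], `[[`, 0, "board_temp_C")
    if (length(unique(temps)) < 2L)
      stop(sprintf("dark library needs >= 2 temperatures at t_int = %g s", t),
           call. = FALSE)
  }
  structure(list(frames = frames), class = "dark_library")
}

#' Look up a dark spectrum
#'
#' Selects the library frames at the requested integration time and linearly
#' interpolates per wavelength in board temperature between the bracketing
#' frames; temperatures outside the library range are clamped to the nearest
#' frame.
#'
#' @param lib A `dark_library`.
#' @param t_int Integration time in seconds (must exist in the library).
#' @param temp_C Board temperature in degrees Celsius.
#' @return A `spectrum` of dark counts.
#' @export
lookup_dark <- function(lib, t_int, temp_C) {
  stopifnot(inherits(lib, "dark_library"))
  tint <- vapply(lib$frames, `[[`, 0, "integration_time_s")
  sel <- lib$frames[abs(tint - t_int) < 1e-12]
  if (length(sel) == 0L)
    stop(sprintf("no dark frames at integration time %g s", t_int),
         call. = FALSE)
  temps <- vapply(sel, `[[`, 0, "board_temp_C")
  o <- order(temps)
  sel <- sel[o]; temps <- temps[o]
  tc <- min(max(temp_C, temps[1]), temps[length(temps)])   # clamp
  hi <- which(temps >= tc)[1]
  if (temps[hi] == tc || hi == 1L) {
    v <- sel[[hi]]$dark_counts$values
    if (temps[hi] != tc && hi > 1L) v <- sel[[hi - 1L]]$dark_counts$values
  } else {
    lo <- hi - 1L
    f <- (tc - temps[lo]) / (temps[hi] - temps[lo])
    v <- (1 - f) * sel[[lo]]$dark_counts$values +
      f * sel[[hi]]$dark_counts$values
  }
  spectrum(sel[[1]]$dark_counts$wavelength_nm, v, "counts")
}

#' Estimate an additive wavelength-calibration shift from a line-source frame
#'
#' Detects emission-line peaks in a measured lamp spectrum (local maxima above
#' five times the median absolute level, centroid refined by 3-point parabolic
#' interpolation), pairs each known reference line with the nearest detected
#' peak inside `match_window_nm`, and reports the mean and SD of
#' (reference - detected) over the matched pairs. A positive shift means the
#' measured grid must be increased to align with the reference lines.
#'
#' @param measured A `spectrum` of the line source.
#' @param known_lines_nm Sorted, distinct reference line positions in nm
#'   (e.g. Hg: 404.7, 435.8, 546.1, 579; Ar: 696.5, 706.7, 727.3, 738.4, 763.5).
#' @param match_window_nm Maximum |reference - peak| for a pair; default 5 nm.
#' @return A list with `shift_nm`, `sd_nm` and `n_matched`.
#' @export
estimate_wavelength_shift <- function(measured, known_lines_nm,
                                      match_window_nm = 5) {
  stopifnot(inherits(measured, "spectrum"))
  if (is.unsorted(known_lines_nm, strictly = TRUE))
    stop("reference lines must be sorted and distinct", call. = FALSE)
  pk <- detect_peaks(measured)
  if (length(pk) < 2L)
    stop("fewer than 2 peaks detected in the line-source spectrum",
         call. = FALSE)
  deltas <- vapply(known_lines_nm, function(l) {
    d <- pk - l
    i <- which.min(abs(d))
    if (abs(d[i]) <= match_window_nm) l - pk[i] else NA_real_
  }, 0)
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < 2L)
    stop("fewer than 2 reference lines matched a detected peak", call. = FALSE)
  list(shift_nm = mean(deltas), sd_nm = stats::sd(deltas),
       n_matched = length(deltas))
}

# local maxima above 5x median absolute level, parabolic 3-point refinement
detect_peaks <- function(s) {
  v <- s$values; w <- s$wavelength_nm; n <- length(v)
  thr <- 5 * stats::median(abs(v))
  i <- which(v[-c(1, 2)] < v[-c(1, n)] & v[-c(n - 1, n)] < v[-c(1, n)]) + 1L
  i <- i[v[i] > thr]
  vapply(i, function(j) {
    den <- v[j - 1] - 2 * v[j] + v[j + 1]
    delta <- if (den == 0) 0 else 0.5 * (v[j - 1] - v[j + 1]) / den
    step <- (w[j + 1] - w[j - 1]) / 2
    w[j] + delta * step
  }, 0)
}

#' Radiometric correction factors
#'
#' Multiplicative factors on a 1-nm grid mapping dark-corrected counts per
#' second to spectral radiance (W m^-2 sr^-1 nm^-1 per count s^-1).
#'
#' @param wavelength_nm Strictly increasing 1-nm wavelengths.
#' @param factors Strictly positive, finite factors.
#' @return A `correction_factors` object.
#' @export
correction_factors <- function(wavelength_nm, factors) {
  stopifnot(length(wavelength_nm) == length(factors))
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("correction factors must be positive and finite", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 factors = as.numeric(factors)),
            class = "correction_factors")
}

#' Derive correction factors from a calibration-source measurement
#'
#' The factor at each wavelength is the ratio of the known source spectrum to
#' the measured (dark-corrected, count-rate) spectrum, on their common 1-nm
#' grid. Wavelengths where the measurement is not positive are masked out.
#'
#' @param measured,reference `spectrum` objects on a common 1-nm range.
#' @return A `correction_factors` object.
#' @export
derive_correction_factors <- function(measured, reference) {
  stopifnot(inherits(measured, "spectrum"), inherits(reference, "spectrum"))
  common <- intersect(measured$wavelength_nm, reference$wavelength_nm)
  if (length(common) == 0L)
    stop("measured and reference spectra do not overlap", call. = FALSE)
  m <- measured$values[match(common, measured$wavelength_nm)]
  r <- reference$values[match(common, reference$wavelength_nm)]
  keep <- m > 0
  if (!any(keep))
    stop("measured spectrum not positive anywhere in the overlap",
         call. = FALSE)
  correction_factors(common[keep], r[keep] / m[keep])
}

#' Splice short-, mid- and long-wavelength correction factors
#'
#' Brings the short- and long-wavelength factor sets onto the absolute scale
#' of the mid set by a least-squares scalar computed over the +/- `halfwidth_nm`
#' window around the relevant transition, then blends with a linear weighting
#' ramp across the same window (equal weighting exactly at the transition
#' wavelength). Outside the ramps each region's own factors are used.
#'
#' @param short_cf,mid_cf,long_cf `correction_factors` for the UV-rich,
#'   absolutely calibrated, and IR-rich sources respectively.
#' @param transitions_nm Two transition wavelengths, default `c(400, 760)`.
#' @param halfwidth_nm Ramp half width, default 20 nm.
#' @return A list with the blended `correction_factors` and the two scalars
#'   (`scale_short`, `scale_long`).
#' @export
splice_corrections <- function(short_cf, mid_cf, long_cf,
                               transitions_nm = c(400, 760),
                               halfwidth_nm = 20) {
  stopifnot(inherits(short_cf, "correction_factors"),
            inherits(mid_cf, "correction_factors"),
            inherits(long_cf, "correction_factors"),
            length(transitions_nm) == 2, diff(transitions_nm) > 0)
  t1 <- transitions_nm[1]; t2 <- transitions_nm[2]; h <- halfwidth_nm

  ls_scale <- function(outer, t) {
    w <- seq(t - h, t + h)
    oi <- match(w, outer$wavelength_nm); mi <- match(w, mid_cf$wavelength_nm)
    if (anyNA(oi) || anyNA(mi))
      stop(sprintf("splice window around %g nm not covered by both segments", t),
           call. = FALSE)
    o <- outer$factors[oi]; m <- mid_cf$factors[mi]
    sum(o * m) / sum(o * o)
  }
  s_short <- ls_scale(short_cf, t1)
  s_long <- ls_scale(long_cf, t2)

  grid <- sort(unique(c(short_cf$wavelength_nm, mid_cf$wavelength_nm,
                        long_cf$wavelength_nm)))
  val_at <- function(cf, scale) {
    v <- rep(NA_real_, length(grid))
    i <- match(cf$wavelength_nm, grid)
    v[i] <- cf$factors * scale
    v
  }
  vs <- val_at(short_cf, s_short)
  vm <- val_at(mid_cf, 1)
  vl <- val_at(long_cf, s_long)

  w1 <- pmin(pmax((grid - (t1 - h)) / (2 * h), 0), 1)  # 0 = short, 1 = mid
  w2 <- pmin(pmax((grid - (t2 - h)) / (2 * h), 0), 1)  # 0 = mid, 1 = long
  out <- ifelse(grid < t1 - h, vs,
         ifelse(grid <= t1 + h, (1 - w1) * vs + w1 * vm,
         ifelse(grid < t2 - h, vm,
         ifelse(grid <= t2 + h, (1 - w2) * vm + w2 * vl, vl))))
  keep <- !is.na(out)
  list(cf = correction_factors(grid[keep], out[keep]),
       scale_short = s_short, scale_long = s_long)
}

#' Windowed odd/even correlation as a signal-quality diagnostic
#'
#' At each wavelength of a 1-nm-gridded spectrum, the absolute Pearson
#' correlation between the samples at odd and at even nanometre wavelengths
#' inside a +/- `halfwidth_nm` window. Smooth, well-measured source spectra
#' give correlations near 1; pure noise gives values near 0. The two parity
#' sets are truncated to equal length at the window edge; windows with fewer
#' than 4 samples, or with zero variance in either set, are flagged `NA`.
#'
#' @param s A `spectrum` on a 1-nm grid.
#' @param halfwidth_nm Window half width, default 20 nm.
#' @return A data frame with columns `wavelength_nm` and `abs_corr`.
#' @export
window_snr <- function(s, halfwidth_nm = 20) {
  stopifnot(inherits(s, "spectrum"))
  w <- s$wavelength_nm
  if (any(abs(diff(w) - 1) > 1e-9))
    stop("window_snr requires a 1-nm grid", call. = FALSE)
  r <- vapply(seq_along(w), function(i) {
    idx <- which(w >= w[i] - halfwidth_nm & w <= w[i] + halfwidth_nm)
    if (length(idx) < 4L) return(NA_real_)
    odd <- s$values[idx[round(w[idx]) %% 2 == 1]]
    even <- s$values[idx[round(w[idx]) %% 2 == 0]]
    k <- min(length(odd), length(even))
    if (k < 2L) return(NA_real_)
    odd <- odd[seq_len(k)]; even <- even[seq_len(k)]
    if (stats::sd(odd) == 0 || stats::sd(even) == 0) return(NA_real_)
    abs(stats::cor(odd, even))
  }, 0)
  data.frame(wavelength_nm = w, abs_corr = r)
}

#' Raw spectrometer frame
#'
#' Uncalibrated counts on the instrument's factory wavelength grid, together
#' with the acquisition parameters needed to calibrate them.
#'
#' @param counts A `spectrum` with units `"counts"` on the factory grid
#'   (possibly non-uniform).
#' @param integration_time_s Integration time in seconds.
#' @param board_temp_C Board temperature in degrees Celsius.
#' @param instrument_id Instrument label, e.g. `"A"` or `"B"`.
#' @param saturation_level ADC full scale; default 65535 (16-bit).
#' @return A `raw_frame` object.
#' @export
raw_frame <- function(counts, integration_time_s, board_temp_C,
                      instrument_id = "A", saturation_level = 65535) {
  stopifnot(inherits(counts, "spectrum"), integration_time_s > 0)
  if (counts$units != "counts")
    stop("raw frames must be in counts", call. = FALSE)
  if (any(counts$values < 0) || any(counts$values > saturation_level))
    stop("counts must lie within [0, saturation_level]", call. = FALSE)
  structure(list(counts = counts, integration_time_s = integration_time_s,
                 board_temp_C = board_temp_C, instrument_id = instrument_id,
                 saturation_level = saturation_level),
            class = "raw_frame")
}

#' Calibrate a raw frame to spectral irradiance
#'
#' The full correction chain for one frame: (1) subtract the interpolated dark
#' spectrum; (2) divide by the integration time; (3) apply the additive
#' wavelength-shift correction to the factory grid and resample to the 1-nm
#' grid of the correction factors; (4) multiply by the correction factors,
#' giving radiance in W m^-2 sr^-1 nm^-1; (5) multiply by pi (the projected
#' solid angle over a hemisphere), giving downwelling irradiance in
#' W m^-2 nm^-1.
#'
#' @param raw A `raw_frame`.
#' @param lib A `dark_library` for the frame's instrument.
#' @param shift_nm Additive wavelength shift (positive increases the grid).
#' @param cf `correction_factors` on the target 1-nm grid.
#' @return A `spectrum` with units `"irradiance_W_m2_nm"`, on the part of the
#'   correction-factor grid covered by the shifted frame.
#' @export
process_raw <- function(raw, lib, shift_nm, cf) {
  stopifnot(inherits(raw, "raw_frame"), inherits(cf, "correction_factors"))
  dark <- lookup_dark(lib, raw$integration_time_s, raw$board_temp_C)
  if (length(dark$values) != length(raw$counts$values))
    stop("dark spectrum grid does not match the raw frame grid", call. = FALSE)
  rate <- (raw$counts$values - dark$values) / raw$integration_time_s
  grid_true <- raw$counts$wavelength_nm + shift_nm
  target <- cf$wavelength_nm[cf$wavelength_nm >= min(grid_true) &
                               cf$wavelength_nm <= max(grid_true)]
  if (length(target) < 2L)
    stop("correction factors do not cover the shifted frame grid",
         call. = FALSE)
  v <- stats::approx(grid_true, rate, xout = target)$y
  fac <- cf$factors[match(target, cf$wavelength_nm)]
  spectrum(target, v * fac * pi, "irradiance_W_m2_nm")
}

#' Quality-control filter and batch calibration
#'
#' Applies the acceptance rules to a set of raw frames: frames with any count
#' at or above the saturation level are discarded; survivors are calibrated
#' with [process_raw()]; negative post-dark values are clamped to zero; frames
#' that are zero at every wavelength after clamping are discarded; the
#' remaining spectra are median-filtered (order 8). Rejections are reported,
#' not raised.
#'
#' @param frames A (possibly named) list of `raw_frame` objects.
#' @param lib A `dark_library`.
#' @param shift_nm Additive wavelength shift for this instrument.
#' @param cf `correction_factors` for this instrument.
#' @param median_order Order of the final median filter; default 8.
#' @return A list with `kept` (named list of irradiance `spectrum` objects)
#'   and `rejected` (data frame of `id`, `reason`).
#' @export
qc_filter <- function(frames, lib, shift_nm, cf, median_order = 8) {
  ids <- names(frames)
  if (is.null(ids)) ids <- as.character(seq_along(frames))
  kept <- list()
  rej_id <- character(0); rej_reason <- character(0)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (any(f$counts$values >= f$saturation_level)) {
      rej_id <- c(rej_id, ids[k]); rej_reason <- c(rej_reason, "saturated")
      next
    }
    s <- process_raw(f, lib, shift_nm, cf)
    s$values[s$values < 0] <- 0
    if (all(s$values == 0)) {
      rej_id <- c(rej_id, ids[k])
      rej_reason <- c(rej_reason, "all_zero_after_dark_subtraction")
      next
    }
    kept[[ids[k]]] <- median_filter(s, median_order)
  }
  list(kept = kept,
       rejected = data.frame(id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}
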