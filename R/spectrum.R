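#' Spectra as wavelength-indexed vectors
#'
#' A `spectrum` is the package's basic container: a strictly increasing
#' wavelength grid (nm), a numeric value per wavelength, and a units tag.
#' All pipeline stages (calibration, colorimetry, model fitting) operate on
#' this class or on matrices of spectra sharing one grid.
#'
#' @param wavelength_nm Strictly increasing numeric vector of wavelengths (nm),
#'   length >= 2.
#' @param values Numeric vector of the same length; must be finite.
#' @param units One of `"counts"`, `"counts_per_s"`, `"radiance_W_m2_sr_nm"`,
#'   `"irradiance_W_m2_nm"`, `"relative"`.
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(400:700, rep(1, 301), "relative")
#' @export
spectrum <- function(wavelength_nm, values,
                     units = c("relative", "counts", "counts_per_s",
                               "radiance_W_m2_sr_nm", "irradiance_W_m2_nm")) {
  units <- match.arg(units)
  wavelength_nm <- as.numeric(wavelength_nm)
  values <- as.numeric(values)
  if (length(wavelength_nm) < 2L)
    stop("spectrum needs at least 2 wavelengths", call. = FALSE)
  if (length(values) != length(wavelength_nm))
    stop("wavelength and value vectors differ in length", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectrum values must be finite", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, values = values, units = units),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d samples, %.5g-%.5g nm, units: %s\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$units))
  invisible(x)
}

#' Wavelength band
#'
#' @param lo_nm,hi_nm Band edges in nm, `lo_nm < hi_nm`.
#' @param label Optional text label (e.g. `"VIS"`).
#' @return A `wavelength_band` object. Standard bands used throughout:
#'   VIS 400-800 nm, UV-A 315-400 nm, UV-B 280-315 nm.
#' @export
wavelength_band <- function(lo_nm, hi_nm, label = "") {
  if (!(lo_nm < hi_nm)) stop("band requires lo_nm < hi_nm", call. = FALSE)
  structure(list(lo_nm = lo_nm, hi_nm = hi_nm, label = label),
            class = "wavelength_band")
}

#' Resample a spectrum to a 1-nm grid
#'
#' Linear interpolation onto the integer-step grid `lo_nm, lo_nm + 1, ..., hi_nm`,
#' the common grid used by every downstream stage. The requested range must lie
#' within the support of the source grid; no extrapolation is performed.
#'
#' @param s A `spectrum`.
#' @param lo_nm,hi_nm Grid end points (nm).
#' @return A `spectrum` on the 1-nm grid, units preserved.
#' @export
resample_1nm <- function(s, lo_nm, hi_nm) {
  stopifnot(inherits(s, "spectrum"))
  if (lo_nm < min(s$wavelength_nm) || hi_nm > max(s$wavelength_nm))
    stop(sprintf("requested range [%g, %g] outside source support [%g, %g]",
                 lo_nm, hi_nm, min(s$wavelength_nm), max(s$wavelength_nm)),
         call. = FALSE)
  grid <- seq(lo_nm, hi_nm, by = 1)
  v <- stats::approx(s$wavelength_nm, s$values, xout = grid)$y
  spectrum(grid, v, s$units)
}

#' Median-filter a spectrum
#'
#' Moving-window median of length `order + 1` (an 8th-order filter uses a
#' 9-point window), the same smoother applied to every calibration and field
#' spectrum before analysis. Windows are truncated at the array boundaries:
#' each output sample is the median of the available samples in
#' `[i - order/2, i + order/2]`, with R's convention (mean of the two middle
#' values) for even counts.
#'
#' @param s A `spectrum`.
#' @param order Filter order (window length minus one); default 8.
#' @return The filtered `spectrum` on the unchanged grid.
#' @export
median_filter <- function(s, order = 8) {
  stopifnot(inherits(s, "spectrum"), order >= 1)
  spectrum(s$wavelength_nm, median_filter_values(s$values, order), s$units)
}

# window +/- floor/ceiling split of `order` samples around each index,
# truncated at the edges; interior fast path via stats::runmed when the
# window length is odd.
median_filter_values <- function(x, order = 8) {
  n <- length(x)
  half_lo <- floor(order / 2)
  half_hi <- ceiling(order / 2)
  k <- order + 1L
  out <- numeric(n)
  if (half_lo == half_hi && k <= n) {       # odd window: runmed interior
    out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
    edge <- c(seq_len(min(half_lo, n)), seq.int(max(n - half_lo + 1L, 1L), n))
  } else {
    edge <- seq_len(n)
  }
  for (i in unique(edge)) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    out[i] <- stats::median(x[lo:hi])
  }
  out
}

#' L2-normalise a spectrum
#'
#' Divides by the Euclidean norm over the spectrum's grid, the normalisation
#' applied to both measured spectra and basis functions before model fitting.
#'
#' @param s A `spectrum` with at least one non-zero value.
#' @return A list with `spectrum` (unit norm, units `"relative"`) and `norm`
#'   (the divisor, i.e. the scale factor mapping back to the input).
#' @export
l2_normalize <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  nrm <- sqrt(sum(s$values^2))
  if (nrm == 0) stop("cannot normalise an all-zero spectrum", call. = FALSE)
  list(spectrum = spectrum(s$wavelength_nm, s$values / nrm, "relative"),
       norm = nrm)
}

#' Band-integrated irradiance
#'
#' Trapezoidal integral of spectral irradiance over a wavelength band,
#' in W m^-2. Used for the VIS (400-800 nm), UV-A (315-400 nm) and UV-B
#' (280-315 nm) intensity summaries.
#'
#' @param s A `spectrum` with units `"irradiance_W_m2_nm"`.
#' @param band A `wavelength_band` overlapping the grid.
#' @return The integral in W m^-2.
#' @export
band_irradiance <- function(s, band) {
  stopifnot(inherits(s, "spectrum"), inherits(band, "wavelength_band"))
  if (s$units != "irradiance_W_m2_nm")
    stop("band_irradiance requires irradiance units, got: ", s$units,
         call. = FALSE)
  lo <- max(band$lo_nm, min(s$wavelength_nm))
  hi <- min(band$hi_nm, max(s$wavelength_nm))
  if (lo >= hi)
    stop("band does not overlap the spectrum's grid", call. = FALSE)
  keep <- s$wavelength_nm > lo & s$wavelength_nm < hi
  w <- c(lo, s$wavelength_nm[keep], hi)
  v <- c(stats::approx(s$wavelength_nm, s$values, lo)$y,
         s$values[keep],
         stats::approx(s$wavelength_nm, s$values, hi)$y)
  trapezoid(w, v)
}

trapezoid <- function(w, v) sum(diff(w) * (v[-1] + v[-length(v)]) / 2)

#' Normalise a spectrum to 1 at an anchor wavelength
#'
#' Divides by the value at `anchor_nm` (555 nm by default, the convention used
#' to display spectral composition independent of intensity). The anchor must
#' be an exact grid point with a positive value.
#'
#' @param s A `spectrum`.
#' @param anchor_nm Anchor wavelength; must lie on the grid.
#' @return The anchored `spectrum` (units `"relative"`).
#' @export
normalize_at <- function(s, anchor_nm = 555) {
  stopifnot(inherits(s, "spectrum"))
  i <- match(anchor_nm, s$wavelength_nm)
  if (is.na(i))
    stop("anchor wavelength ", anchor_nm, " nm is not a grid point",
         call. = FALSE)
  if (s$values[i] <= 0)
    stop("value at anchor is not positive; cannot anchor-normalise",
         call. = FALSE)
  spectrum(s$wavelength_nm, s$values / s$values[i], "relative")
}
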