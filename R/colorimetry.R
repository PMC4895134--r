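#' CIE 1931 colour-matching functions
#'
#' The standard 2-degree observer, tabulated at 5 nm in the package fixtures
#' and linearly interpolated to the 1-nm grid 360-830 nm. Cached after the
#' first call.
#'
#' @return A list with `wavelength_nm` (360:830) and matrix `cmf` with
#'   columns `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function() {
  if (is.null(.skyspec_cache$cmf)) {
    path <- system.file("extdata", "cie1931_cmf_2deg_5nm.csv",
                        package = "skyspec", mustWork = TRUE)
    tab <- utils::read.csv(path)
    wl <- 360:830
    cmf <- vapply(c("xbar", "ybar", "zbar"),
                  function(k) stats::approx(tab$wavelength_nm, tab[[k]], wl)$y,
                  numeric(length(wl)))
    .skyspec_cache$cmf <- list(wavelength_nm = wl, cmf = cmf)
  }
  .skyspec_cache$cmf
}

.skyspec_cache <- new.env(parent = emptyenv())

#' Tristimulus values of a spectrum
#'
#' Summation of the spectrum against the colour-matching functions over their
#' common 1-nm grid: X = sum s(l) xbar(l), and similarly Y, Z.
#'
#' @param s A `spectrum` on a 1-nm grid overlapping 360-830 nm.
#' @param cmf Colour-matching functions as returned by [cie_cmf()].
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
xyz_from_spectrum <- function(s, cmf = cie_cmf()) {
  stopifnot(inherits(s, "spectrum"))
  common <- intersect(s$wavelength_nm, cmf$wavelength_nm)
  if (length(common) == 0L)
    stop("spectrum does not overlap the colour-matching functions",
         call. = FALSE)
  v <- s$values[match(common, s$wavelength_nm)]
  m <- cmf$cmf[match(common, cmf$wavelength_nm), , drop = FALSE]
  c(X = sum(v * m[, "xbar"]), Y = sum(v * m[, "ybar"]),
    Z = sum(v * m[, "zbar"]))
}

#' Chromaticity coordinates from tristimulus values
#'
#' @param X,Y,Z Tristimulus values with `X + Y + Z > 0` (vectorised).
#' @return A data frame with columns `x` and `y`.
#' @export
xy_from_xyz <- function(X, Y, Z) {
  s <- X + Y + Z
  if (any(s <= 0))
    stop("X + Y + Z must be positive for chromaticity", call. = FALSE)
  data.frame(x = X / s, y = Y / s)
}

# classical daylight-locus chromaticity polynomials and component weights
daylight_xy <- function(cct_K) {
  if (any(cct_K < 4000 | cct_K > 25000))
    stop("CCT must lie within [4000, 25000] K", call. = FALSE)
  x <- ifelse(cct_K <= 7000,
              0.244063 + 0.09911e3 / cct_K + 2.9678e6 / cct_K^2 -
                4.6070e9 / cct_K^3,
              0.237040 + 0.24748e3 / cct_K + 1.9018e6 / cct_K^2 -
                2.0064e9 / cct_K^3)
  y <- -3.000 * x^2 + 2.870 * x - 0.275
  data.frame(x = x, y = y)
}

daylight_weights <- function(xD, yD) {
  den <- 0.0241 + 0.2562 * xD - 0.7341 * yD
  list(M1 = (-1.3515 - 1.7703 * xD + 5.9114 * yD) / den,
       M2 = (0.0300 - 31.4424 * xD + 30.0717 * yD) / den)
}

# classical (un-normalised) S0/S1/S2 daylight components on the 1-nm grid
cie_daylight_components <- function(lo_nm = 360, hi_nm = 830) {
  key <- paste0("S_", lo_nm, "_", hi_nm)
  if (is.null(.skyspec_cache[[key]])) {
    path <- system.file("extdata", "cie_daylight_components_10nm.csv",
                        package = "skyspec", mustWork = TRUE)
    tab <- utils::read.csv(path)
    wl <- seq(lo_nm, hi_nm, by = 1)
    .skyspec_cache[[key]] <- list(
      wavelength_nm = wl,
      S = vapply(c("S0", "S1", "S2"),
                 function(k) stats::approx(tab$wavelength_nm, tab[[k]], wl)$y,
                 numeric(length(wl))))
  }
  .skyspec_cache[[key]]
}

#' CIE daylight spectral power distribution at a given CCT
#'
#' The standard construction: the daylight-locus chromaticity `x_D` from the
#' published CCT polynomial, `y_D = -3 x_D^2 + 2.87 x_D - 0.275`, the weights
#' `M1`, `M2` from `(x_D, y_D)`, and the spectrum `S0 + M1 S1 + M2 S2` using
#' the classical (un-normalised) component tables.
#'
#' @param cct_K Correlated colour temperature in [4000, 25000] K.
#' @param lo_nm,hi_nm Output grid end points (1-nm spacing).
#' @return A `spectrum` with units `"relative"`.
#' @export
cie_daylight_spectrum <- function(cct_K, lo_nm = 360, hi_nm = 830) {
  xy <- daylight_xy(cct_K)
  w <- daylight_weights(xy$x, xy$y)
  comp <- cie_daylight_components(lo_nm, hi_nm)
  spectrum(comp$wavelength_nm,
           comp$S[, "S0"] + w$M1 * comp$S[, "S1"] + w$M2 * comp$S[, "S2"],
           "relative")
}

#' Chromaticities along the CIE daylight locus
#'
#' @param cct_grid CCTs in kelvin, each within [4000, 25000].
#' @return Data frame with `cct_K`, `x`, `y`: the chromaticity of the
#'   constructed daylight spectrum at each CCT, computed through the
#'   colour-matching functions.
#' @export
daylight_locus <- function(cct_grid) {
  xs <- vapply(cct_grid, function(cct) {
    xyz <- xyz_from_spectrum(cie_daylight_spectrum(cct))
    unlist(xy_from_xyz(xyz["X"], xyz["Y"], xyz["Z"]))
  }, c(x = 0, y = 0))
  data.frame(cct_K = cct_grid, x = xs["x", ], y = xs["y", ])
}

# linear-sRGB matrix (D65) and gamma encoding
.srgb_matrix <- matrix(c(3.2406, -1.5372, -0.4986,
                         -0.9689, 1.8758, 0.0415,
                         0.0557, -0.2040, 1.0570),
                       nrow = 3, byrow = TRUE)

srgb_encode <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Pseudo-colour sRGB rendering of binned spectra
#'
#' Renders a set of L2-normalised bin-average spectra as sRGB swatches whose
#' lightness tracks the bins' absolute intensity: the log10 of the
#' normalising L2 norms is mapped linearly onto [0.3, 1], each unit spectrum
#' is multiplied by its mapped value, XYZ tristimulus values are computed,
#' Y is scaled so the brightest bin has Y = 1, and the standard linear
#' XYZ-to-sRGB transform plus gamma encoding is applied with hard per-channel
#' clipping to [0, 1]. If all norms are equal every scale is set to 1.
#'
#' @param spectra List of `spectrum` objects (unit L2 norm, common 1-nm grid).
#' @param norms Positive L2 norms, one per spectrum.
#' @return A data frame with columns `R`, `G`, `B` in [0, 1], one row per bin.
#' @export
render_srgb <- function(spectra, norms) {
  stopifnot(length(spectra) >= 2, length(norms) == length(spectra),
            all(norms > 0))
  ln <- log10(norms)
  scale <- if (diff(range(ln)) == 0) rep(1, length(ln)) else
    0.3 + 0.7 * (ln - min(ln)) / (max(ln) - min(ln))
  xyz <- t(vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    xyz_from_spectrum(spectrum(s$wavelength_nm, s$values * scale[i],
                               "relative"))
  }, c(X = 0, Y = 0, Z = 0)))
  xyz <- xyz / max(xyz[, "Y"])
  rgb_lin <- xyz %*% t(.srgb_matrix)
  out <- as.data.frame(apply(rgb_lin, 2, srgb_encode))
  names(out) <- c("R", "G", "B")
  attr(out, "scale") <- scale
  out
}
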