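#' Basis sets of illumination components
#'
#' An ordered set of named component spectra on a common 1-nm grid, each
#' stored with unit Euclidean norm, together with the wavelength range over
#' which models are fitted. Houses the CIE daylight components S0, S1, S2 and
#' any components derived from residuals.
#'
#' @param name Basis-set name.
#' @param wavelength_nm Common 1-nm grid.
#' @param components Numeric matrix, one column per component.
#' @param component_names Optional column names.
#' @param fit_range_nm Length-2 range used for fitting; defaults to the grid
#'   span.
#' @param normalize If `TRUE` (default) columns are divided by their L2 norms.
#' @return A `basis_set` object.
#' @export
basis_set <- function(name, wavelength_nm, components, component_names = NULL,
                      fit_range_nm = range(wavelength_nm), normalize = TRUE) {
  components <- as.matrix(components)
  stopifnot(nrow(components) == length(wavelength_nm))
  if (!is.null(component_names)) colnames(components) <- component_names
  if (is.null(colnames(components)))
    colnames(components) <- paste0("c", seq_len(ncol(components)))
  if (normalize) {
    nrm <- sqrt(colSums(components^2))
    if (any(nrm == 0)) stop("zero-norm basis component", call. = FALSE)
    components <- sweep(components, 2, nrm, "/")
  }
  structure(list(name = name, wavelength_nm = as.numeric(wavelength_nm),
                 components = components, fit_range_nm = fit_range_nm),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> '%s': %d components [%s], %g-%g nm\n", x$name,
              ncol(x$components), paste(colnames(x$components), collapse = ", "),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' The CIE daylight basis (S0, S1, S2), L2-normalised
#'
#' The classical daylight components interpolated to a 1-nm grid over the fit
#' range and normalised to unit vector norm, as used for all model fitting.
#' (The un-normalised tables are retained separately for the daylight-spectrum
#' construction in [cie_daylight_spectrum()], whose M1/M2 weight formulas
#' assume the classical scaling.)
#'
#' @param fit_range_nm Fitting range; 360-830 nm for this instrument class,
#'   380-780 nm for the external daylight databases.
#' @return A `basis_set` with components S0, S1, S2.
#' @export
load_cie_basis <- function(fit_range_nm = c(360, 830)) {
  comp <- cie_daylight_components(fit_range_nm[1], fit_range_nm[2])
  basis_set("CIE", comp$wavelength_nm, comp$S,
            component_names = c("S0", "S1", "S2"),
            fit_range_nm = fit_range_nm)
}

# resample a list of spectra onto the basis grid (fit range), as columns
spectra_matrix <- function(spectra, basis) {
  lo <- basis$fit_range_nm[1]; hi <- basis$fit_range_nm[2]
  grid <- basis$wavelength_nm[basis$wavelength_nm >= lo &
                                basis$wavelength_nm <= hi]
  Y <- vapply(spectra, function(s) {
    stats::approx(s$wavelength_nm, s$values, xout = grid)$y
  }, numeric(length(grid)))
  if (anyNA(Y))
    stop("a spectrum does not cover the basis fit range", call. = FALSE)
  list(grid = grid, Y = matrix(Y, nrow = length(grid)))
}

# core least-squares engine on column-normalised spectra.
# Returns weights (k x n), fitted (p x n), scales, r2 (field convention:
# squared Pearson correlation between fit and data) and r2_sse (1 - SSE/SST).
fit_engine <- function(basis, Y) {
  lo <- basis$fit_range_nm[1]; hi <- basis$fit_range_nm[2]
  sel <- basis$wavelength_nm >= lo & basis$wavelength_nm <= hi
  B <- basis$components[sel, , drop = FALSE]
  stopifnot(nrow(B) == nrow(Y))
  d <- svd(B, nu = 0, nv = 0)$d
  if (d[length(d)] == 0 || d[1] / d[length(d)] > 1e10)
    stop("basis is rank deficient (condition number > 1e10)", call. = FALSE)
  scales <- sqrt(colSums(Y^2))
  if (any(scales == 0))
    stop("cannot fit an all-zero spectrum", call. = FALSE)
  Yn <- sweep(Y, 2, scales, "/")
  qrB <- qr(B)
  W <- qr.coef(qrB, Yn)
  fitted <- B %*% W
  r2 <- vapply(seq_len(ncol(Yn)), function(j) {
    if (stats::sd(fitted[, j]) == 0 || stats::sd(Yn[, j]) == 0) return(0)
    stats::cor(fitted[, j], Yn[, j])^2
  }, 0)
  sse <- colSums((Yn - fitted)^2)
  sst <- colSums(sweep(Yn, 2, colMeans(Yn))^2)
  list(weights = matrix(W, ncol = ncol(Yn),
                        dimnames = list(colnames(basis$components), NULL)),
       fitted = fitted, normalized = Yn, scale = scales,
       r_squared = r2, r_squared_sse = 1 - sse / sst, sse = sse)
}

#' Fit a basis model to one spectrum
#'
#' Resamples the spectrum onto the basis grid over the fit range, normalises
#' it by its vector norm (recording the norm as the scale factor), and finds
#' the least-squares component weights (no intercept). The goodness of fit
#' `r_squared` is the squared Pearson correlation between the fitted and the
#' measured values across wavelengths; `r_squared_sse` (1 - SSE/SST) is also
#' reported since the two differ when the fit is biased.
#'
#' @param basis A `basis_set`.
#' @param s A `spectrum` covering the fit range.
#' @return A `fit_result` list: `weights`, `scale`, `r_squared`,
#'   `r_squared_sse`, `fitted`, `residual` (both on the normalised scale).
#' @export
fit_spectrum <- function(basis, s) {
  stopifnot(inherits(basis, "basis_set"), inherits(s, "spectrum"))
  sm <- spectra_matrix(list(s), basis)
  f <- fit_engine(basis, sm$Y)
  structure(list(weights = stats::setNames(f$weights[, 1],
                                           colnames(basis$components)),
                 scale = f$scale[1], r_squared = f$r_squared[1],
                 r_squared_sse = f$r_squared_sse[1],
                 wavelength_nm = sm$grid, fitted = f$fitted[, 1],
                 residual = f$normalized[, 1] - f$fitted[, 1]),
            class = "fit_result")
}

#' Fit a basis model to a record set, summarised by solar-elevation bin
#'
#' Fits every spectrum as in [fit_spectrum()] and reports the per-bin
#' arithmetic mean and SD of each component weight and of R-squared, together
#' with the mean scale factor, using half-open bins from
#' [bin_by_elevation()]. Empty bins are omitted.
#'
#' @param basis A `basis_set`.
#' @param spectra List of `spectrum` objects.
#' @param theta_s Solar elevation (degrees) per spectrum.
#' @param bin_width_deg Bin width in degrees; default 2.
#' @return A data frame with one row per non-empty bin: `bin_center`, `n`,
#'   `r2_mean`, `r2_sd`, `scale_mean`, and `<component>_mean` / `<component>_sd`
#'   per basis component.
#' @export
fit_set <- function(basis, spectra, theta_s, bin_width_deg = 2) {
  stopifnot(length(spectra) == length(theta_s))
  sm <- spectra_matrix(spectra, basis)
  f <- fit_engine(basis, sm$Y)
  bins <- bin_by_elevation(theta_s, bin_width_deg)
  centers <- sort(unique(bins$bin_center))
  rows <- lapply(centers, function(ctr) {
    j <- which(bins$bin_center == ctr)
    out <- data.frame(bin_center = ctr, n = length(j),
                      r2_mean = mean(f$r_squared[j]),
                      r2_sd = if (length(j) > 1) stats::sd(f$r_squared[j]) else 0,
                      scale_mean = mean(f$scale[j]))
    for (k in seq_len(nrow(f$weights))) {
      nm <- rownames(f$weights)[k]
      out[[paste0(nm, "_mean")]] <- mean(f$weights[k, j])
      out[[paste0(nm, "_sd")]] <- if (length(j) > 1)
        stats::sd(f$weights[k, j]) else 0
    }
    out
  })
  do.call(rbind, rows)
}
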