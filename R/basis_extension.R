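#' Mean fit residual as a new basis component
#'
#' Fits the given basis to every spectrum (on the normalised scale), takes the
#' arithmetic mean of the per-spectrum residuals across spectra, and divides
#' it by its Euclidean norm. The sign is left as computed; downstream fit
#' weights absorb it. Residuals are averaged first and the average is then
#' normalised.
#'
#' @param basis A `basis_set`.
#' @param spectra Non-empty list of `spectrum` objects covering the fit range.
#' @return A list with `component` (unit-norm numeric vector on the fit-range
#'   grid), `wavelength_nm`, and `n` (number of spectra pooled).
#' @export
mean_residual <- function(basis, spectra) {
  if (length(spectra) == 0L)
    stop("cannot extract a residual component from an empty record set",
         call. = FALSE)
  sm <- spectra_matrix(spectra, basis)
  f <- fit_engine(basis, sm$Y)
  m <- rowMeans(f$normalized - f$fitted)
  nrm <- sqrt(sum(m^2))
  if (nrm < 1e-12)
    stop("mean residual is degenerate: spectra lie in the basis span",
         call. = FALSE)
  list(component = m / nrm, wavelength_nm = sm$grid, n = length(spectra))
}

# append a unit-norm component to a basis (grids restricted to the fit range
# must agree)
append_component <- function(basis, component, wavelength_nm, name) {
  sel <- basis$wavelength_nm >= basis$fit_range_nm[1] &
    basis$wavelength_nm <= basis$fit_range_nm[2]
  stopifnot(all(basis$wavelength_nm[sel] == wavelength_nm))
  comp <- basis$components[sel, , drop = FALSE]
  basis_set(name, wavelength_nm, cbind(comp, component),
            component_names = c(colnames(comp), name),
            fit_range_nm = basis$fit_range_nm, normalize = FALSE)
}

#' Derive extended illumination models by iterative residual extraction
#'
#' Grows the 3-component CIE daylight basis into two location-specific
#' 6-component models. Stage 1 pools all rural and city daylight spectra
#' (`theta_s >= 0`), fits the CIE basis and appends the normalised mean
#' residual (CIE+1). Stage 2 pools both locations' civil-twilight spectra
#' (`-6 < theta_s < 0`), fits the CIE+1 model and appends its mean residual
#' (CIE+2). Stage 3 fits the CIE+2 model to each location's astronomical
#' twilight spectra (`-18 < theta_s < -12`) separately and appends the
#' location-specific residual components, yielding CIE+3R (rural) and CIE+3C
#' (city). Nautical-twilight spectra are never used in component derivation.
#' Rural records are expected to be pre-filtered to lunar fraction < 0.3.
#'
#' The stage regimes use strict inequalities for the open intervals, exactly
#' as in the derivation this reproduces.
#'
#' @param rural,city Lists with elements `spectra` (list of `spectrum`) and
#'   `theta_s` (numeric, degrees).
#' @param cie The base `basis_set`, normally [load_cie_basis()].
#' @return A list with `cie_plus_3R`, `cie_plus_3C` (6-component
#'   `basis_set`s), the intermediate `cie_plus_1` and `cie_plus_2`, and
#'   `stages`, a data frame recording each stage's regime and record count.
#' @export
extend_cie <- function(rural, city, cie = load_cie_basis()) {
  pick <- function(set, lo, hi, closed_lo = FALSE) {
    keep <- if (closed_lo) set$theta_s >= lo & set$theta_s < hi
    else set$theta_s > lo & set$theta_s < hi
    set$spectra[keep]
  }
  stage_sets <- list(
    daylight = c(pick(rural, 0, Inf, closed_lo = TRUE),
                 pick(city, 0, Inf, closed_lo = TRUE)),
    civil = c(pick(rural, -6, 0), pick(city, -6, 0)),
    astro_rural = pick(rural, -18, -12),
    astro_city = pick(city, -18, -12))
  for (nm in names(stage_sets))
    if (length(stage_sets[[nm]]) == 0L)
      stop("no spectra in stage regime: ", nm, call. = FALSE)

  r1 <- mean_residual(cie, stage_sets$daylight)
  cie1 <- append_component(cie, r1$component, r1$wavelength_nm, "CIE+1")
  r2 <- mean_residual(cie1, stage_sets$civil)
  cie2 <- append_component(cie1, r2$component, r2$wavelength_nm, "CIE+2")
  r3r <- mean_residual(cie2, stage_sets$astro_rural)
  r3c <- mean_residual(cie2, stage_sets$astro_city)
  cie3r <- append_component(cie2, r3r$component, r3r$wavelength_nm, "CIE+3R")
  cie3c <- append_component(cie2, r3c$component, r3c$wavelength_nm, "CIE+3C")
  cie3r$name <- "CIE+3R"; cie3c$name <- "CIE+3C"

  list(cie_plus_3R = cie3r, cie_plus_3C = cie3c,
       cie_plus_1 = cie1, cie_plus_2 = cie2,
       stages = data.frame(
         stage = c(1, 2, 3, 3),
         component = c("CIE+1", "CIE+2", "CIE+3R", "CIE+3C"),
         regime = c("theta_s >= 0 (pooled)", "-6 < theta_s < 0 (pooled)",
                    "-18 < theta_s < -12 (rural)",
                    "-18 < theta_s < -12 (city)"),
         n_records = c(r1$n, r2$n, r3r$n, r3c$n)))
}

#' Compare goodness-of-fit profiles of competing models
#'
#' Fits each model to every spectrum and reports the per-bin mean R-squared
#' (squared Pearson correlation, the convention used throughout) by solar
#' elevation. Optionally adds the mean-spectrum benchmark: a one-component
#' basis consisting of the normalised mean of the night spectra
#' (`theta_s < -18`), the noise-floor reference for nighttime fits.
#'
#' @param models Named list of `basis_set` objects sharing a fit range.
#' @param spectra List of `spectrum` objects.
#' @param theta_s Solar elevation per spectrum (degrees).
#' @param bin_width_deg Bin width; default 2.
#' @param mean_night_benchmark If `TRUE`, append the mean-night-spectrum
#'   reference model (requires at least one record below -18 degrees).
#' @return A data frame with columns `model`, `bin_center`, `n`, `r2_mean`.
#' @export
compare_models <- function(models, spectra, theta_s, bin_width_deg = 2,
                           mean_night_benchmark = FALSE) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  if (mean_night_benchmark) {
    night <- spectra[theta_s < -18]
    if (length(night) == 0L)
      stop("no night spectra for the mean-spectrum benchmark", call. = FALSE)
    ref <- models[[1]]
    sm <- spectra_matrix(night, ref)
    m <- rowMeans(sweep(sm$Y, 2, sqrt(colSums(sm$Y^2)), "/"))
    models <- c(models, list(
      mean_night = basis_set("mean_night", sm$grid, cbind(mean = m),
                             fit_range_nm = ref$fit_range_nm)))
  }
  out <- lapply(names(models), function(nm) {
    fs <- fit_set(models[[nm]], spectra, theta_s, bin_width_deg)
    data.frame(model = nm, bin_center = fs$bin_center, n = fs$n,
               r2_mean = fs$r2_mean)
  })
  do.call(rbind, out)
}
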