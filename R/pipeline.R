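#' Calibrate every frame of a campaign
#'
#' Per instrument: estimates the wavelength shift from the campaign's
#' calibration-lamp frame, then runs the QC + calibration chain
#' ([qc_filter()]) over that instrument's raw frames with its dark library
#' and response table. Returns calibrated irradiance spectra aligned with the
#' surviving records.
#'
#' @param camp A `sky_campaign` (or the list returned by [read_campaign()]).
#' @return A list with `spectra` (named list of irradiance spectra), `records`
#'   (metadata rows for kept records), `rejected` (QC report), and
#'   `shift_estimates` (per instrument: estimated shift and SD).
#' @export
calibrate_campaign <- function(camp) {
  spectra <- list(); rejected <- list(); shifts <- list()
  for (ins in names(camp$dark_libs)) {
    est <- estimate_wavelength_shift(camp$line_frames[[ins]],
                                     skyspec_reference_lines())
    shifts[[ins]] <- est
    ids <- camp$records$record_id[camp$records$instrument_id == ins]
    if (length(ids) == 0L) next
    qc <- qc_filter(camp$frames[ids], camp$dark_libs[[ins]], est$shift_nm,
                    camp$cf[[ins]])
    spectra <- c(spectra, qc$kept)
    rejected[[ins]] <- qc$rejected
  }
  keep <- camp$records$record_id %in% names(spectra)
  records <- camp$records[keep, , drop = FALSE]
  list(spectra = spectra[records$record_id], records = records,
       rejected = do.call(rbind, rejected), shift_estimates = shifts)
}

#' Per-bin chromaticity of a calibrated record set
#'
#' CIE 1931 xy chromaticity of each spectrum, averaged in solar-elevation
#' bins.
#'
#' @param spectra List of irradiance `spectrum` objects.
#' @param theta_s Solar elevation per spectrum (degrees).
#' @param bin_width_deg Bin width; default 2.
#' @return Data frame with `bin_center`, `n`, `x_mean`, `y_mean`.
#' @export
campaign_chromaticity <- function(spectra, theta_s, bin_width_deg = 2) {
  stopifnot(length(spectra) == length(theta_s))
  xy <- t(vapply(spectra, function(s) {
    xyz <- xyz_from_spectrum(s)
    unlist(xy_from_xyz(xyz["X"], xyz["Y"], xyz["Z"]))
  }, c(x = 0, y = 0)))
  bins <- bin_by_elevation(theta_s, bin_width_deg)
  out <- lapply(sort(unique(bins$bin_center)), function(ctr) {
    j <- bins$bin_center == ctr
    data.frame(bin_center = ctr, n = sum(j), x_mean = mean(xy[j, "x"]),
               y_mean = mean(xy[j, "y"]))
  })
  do.call(rbind, out)
}

#' Band-intensity summary by solar elevation
#'
#' Integrated irradiance in the VIS (400-800 nm), UV-A (315-400 nm) and UV-B
#' (280-315 nm) bands per record, averaged in solar-elevation bins and split
#' by dawn/dusk sequence. Bands not covered by a record's wavelength range
#' (the daylight instrument carries no UV-B) are reported as `NA` and omitted
#' from the averages.
#'
#' @param spectra List of irradiance `spectrum` objects.
#' @param records Metadata with `solar_elevation_deg` and `sequence`.
#' @param bin_width_deg Bin width; default 2.
#' @return Data frame with `bin_center`, `sequence`, `n`, and
#'   `<band>_mean_W_m2` columns (log-averaging is left to the caller).
#' @export
band_intensity_table <- function(spectra, records, bin_width_deg = 2) {
  bands <- list(VIS = wavelength_band(400, 800, "VIS"),
                UVA = wavelength_band(315, 400, "UVA"),
                UVB = wavelength_band(280, 315, "UVB"))
  vals <- vapply(spectra, function(s) {
    vapply(bands, function(b) {
      if (b$lo_nm < min(s$wavelength_nm) - 1e-9) NA_real_
      else band_irradiance(s, b)
    }, 0)
  }, c(VIS = 0, UVA = 0, UVB = 0))
  bins <- bin_by_elevation(records$solar_elevation_deg, bin_width_deg)
  grid <- expand.grid(bin_center = sort(unique(bins$bin_center)),
                      sequence = unique(records$sequence),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    j <- bins$bin_center == grid$bin_center[g] &
      records$sequence == grid$sequence[g]
    if (!any(j)) return(NULL)
    out <- data.frame(bin_center = grid$bin_center[g],
                      sequence = grid$sequence[g], n = sum(j))
    for (b in names(bands))
      out[[paste0(b, "_mean_W_m2")]] <- mean(vals[b, j], na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}

#' End-to-end analysis of a calibrated campaign
#'
#' Runs the full analysis sequence on a campaign: calibration + QC, lunar
#' filtering (rural fraction < `max_lunar_fraction`, city unrestricted),
#' band-intensity and chromaticity summaries, CIE-model fits by location,
#' derivation of the extended CIE+3R / CIE+3C models, model comparison
#' profiles, and the sRGB rendering of the rural elevation bins.
#'
#' @param camp A `sky_campaign`.
#' @param bin_width_deg Bin width for summaries; default 2.
#' @param max_lunar_fraction Strict rural lunar-fraction cut; default 0.3.
#' @return A list of report tables (see element names).
#' @export
analyze_campaign <- function(camp, bin_width_deg = 2,
                             max_lunar_fraction = 0.3) {
  cal <- calibrate_campaign(camp)
  rec <- lunar_filter(cal$records, max_lunar_fraction)
  spectra <- cal$spectra[rec$record_id]
  by_loc <- split(seq_len(nrow(rec)), rec$location_id)

  sets <- lapply(by_loc, function(i)
    list(spectra = spectra[i], theta_s = rec$solar_elevation_deg[i]))
  cie <- load_cie_basis()
  ext <- extend_cie(sets$rural, sets$city, cie)

  fits <- lapply(names(sets), function(loc) {
    full <- if (loc == "rural") ext$cie_plus_3R else ext$cie_plus_3C
    list(cie = fit_set(cie, sets[[loc]]$spectra, sets[[loc]]$theta_s,
                       bin_width_deg),
         extended = fit_set(full, sets[[loc]]$spectra, sets[[loc]]$theta_s,
                            bin_width_deg))
  })
  names(fits) <- names(sets)

  chroma <- lapply(sets, function(s)
    campaign_chromaticity(s$spectra, s$theta_s, bin_width_deg))

  intensity <- lapply(names(sets), function(loc) {
    i <- by_loc[[loc]]
    band_intensity_table(spectra[i], rec[i, , drop = FALSE], bin_width_deg)
  })
  names(intensity) <- names(sets)

  rural_bins <- bin_by_elevation(sets$rural$theta_s, bin_width_deg)
  centers <- sort(unique(rural_bins$bin_center))
  binmean <- lapply(centers, function(ctr) {
    i <- which(rural_bins$bin_center == ctr)
    grid <- sets$rural$spectra[[i[1]]]$wavelength_nm
    m <- rowMeans(vapply(sets$rural$spectra[i], `[[`,
                         numeric(length(grid)), "values"))
    l2_normalize(spectrum(grid, pmax(m, 0) + 1e-300, "relative"))
  })
  srgb <- render_srgb(lapply(binmean, `[[`, "spectrum"),
                      vapply(binmean, `[[`, 0, "norm"))
  srgb <- cbind(bin_center = centers, srgb)

  list(calibration = cal[c("rejected", "shift_estimates")],
       records = rec, spectra = spectra,
       extension = ext, fits = fits, chromaticity = chroma,
       intensity = intensity, srgb_rural = srgb)
}

#' Run the file-based pipeline
#'
#' Reads a campaign directory (the layout written by [write_campaign()]),
#' runs [analyze_campaign()], and writes the report tables, the extended
#' basis sets and a JSON run log (config hash, seed if present, per-stage
#' record counts) to the output directory. Outputs are deterministic given
#' fixed inputs.
#'
#' @param input_dir Campaign directory.
#' @param out_dir Output directory (created if needed).
#' @param bin_width_deg,max_lunar_fraction Passed to [analyze_campaign()].
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, bin_width_deg = 2,
                         max_lunar_fraction = 0.3) {
  camp <- read_campaign(input_dir)
  rep <- analyze_campaign(camp, bin_width_deg, max_lunar_fraction)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  for (loc in names(rep$chromaticity)) {
    w(rep$chromaticity[[loc]], paste0("chromaticity_", loc, ".csv"))
    w(rep$intensity[[loc]], paste0("intensity_", loc, ".csv"))
    w(rep$fits[[loc]]$cie, paste0("fit_cie_", loc, ".csv"))
    w(rep$fits[[loc]]$extended, paste0("fit_extended_", loc, ".csv"))
  }
  write_basis_csv(rep$extension$cie_plus_3R,
                  file.path(out_dir, "basis_cie_plus_3R.csv"))
  write_basis_csv(rep$extension$cie_plus_3C,
                  file.path(out_dir, "basis_cie_plus_3C.csv"))
  w(rep$srgb_rural, "srgb_rural.csv")
  log <- list(
    input_dir = input_dir,
    config_hash = if (!is.null(camp$ground_truth$config_hash))
      camp$ground_truth$config_hash else NA,
    seed = camp$ground_truth$seed,
    shift_estimates = rep$calibration$shift_estimates,
    n_input = length(camp$frames),
    n_rejected = nrow(rep$calibration$rejected),
    n_kept_after_lunar_filter = nrow(rep$records),
    extension_stages = rep$extension$stages)
  write_ledger_json(log, file.path(out_dir, "run_log.json"))
  invisible(rep)
}
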