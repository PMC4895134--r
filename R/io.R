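#' Read and write spectra tables
#'
#' Spectra are serialised as CSV with a `wavelength_nm` first column and one
#' column per measurement id; units are carried by the caller (recorded in
#' the run log / sidecar metadata rather than in the table itself). Floats
#' are written at 17 significant digits for lossless round trips.
#'
#' @param spectra Named list of `spectrum` objects on a common grid.
#' @param path CSV file path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` a named list of `spectrum` objects.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  wl <- spectra[[1]]$wavelength_nm
  for (s in spectra)
    if (!identical(s$wavelength_nm, wl))
      stop("spectra must share one wavelength grid", call. = FALSE)
  df <- data.frame(wavelength_nm = fmt17(wl))
  for (nm in names(spectra)) df[[nm]] <- fmt17(spectra[[nm]]$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' @param units Units tag applied to every spectrum read.
#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, units = "relative") {
  df <- utils::read.csv(path)
  if (names(df)[1] != "wavelength_nm")
    stop("first column must be wavelength_nm: ", path, call. = FALSE)
  if (ncol(df) < 2)
    stop("no spectrum columns in ", path, call. = FALSE)
  out <- lapply(df[-1], function(v) spectrum(df$wavelength_nm, v, units))
  out
}

#' Read and write basis-set CSV files
#'
#' The same wavelength + one-column-per-component layout as spectra tables;
#' this format also accepts externally published models (e.g. a user-supplied
#' six-component daylight basis) for fitting.
#'
#' @param basis A `basis_set`.
#' @param path CSV file path.
#' @param name,fit_range_nm Metadata applied on read.
#' @return The path (write) or a `basis_set` (read).
#' @export
write_basis_csv <- function(basis, path) {
  df <- data.frame(wavelength_nm = fmt17(basis$wavelength_nm))
  for (k in colnames(basis$components)) df[[k]] <- fmt17(basis$components[, k])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_basis_csv
#' @export
read_basis_csv <- function(path, name = basename(path),
                           fit_range_nm = NULL) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "wavelength_nm" || ncol(df) < 2)
    stop("malformed basis table: ", path, call. = FALSE)
  if (is.null(fit_range_nm)) fit_range_nm <- range(df$wavelength_nm)
  basis_set(name, df$wavelength_nm, as.matrix(df[-1]),
            component_names = names(df)[-1], fit_range_nm = fit_range_nm)
}

#' Read and write record-metadata tables
#'
#' ISO-8601 UTC timestamps; the join key to spectra tables is `record_id`.
#'
#' @param records Data frame of record metadata (with POSIXct `timestamp`).
#' @param path CSV file path.
#' @return The path (write) or the records data frame (read).
#' @export
write_records_csv <- function(records, path) {
  df <- records
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  if (anyNA(df$timestamp))
    stop("unparseable timestamp in ", path, call. = FALSE)
  if (!is.null(df$location_id) &&
      !all(df$location_id %in% c("rural", "city")))
    stop("unknown location id in ", path, call. = FALSE)
  df
}

#' Read and write ephemeris tables
#'
#' @param table An `ephemeris_table`.
#' @param path CSV file path.
#' @return The path (write) or an `ephemeris_table` (read).
#' @export
write_ephemeris_csv <- function(table, path) {
  write_records_csv(as.data.frame(table), path)
}

#' @rdname write_ephemeris_csv
#' @export
read_ephemeris_csv <- function(path) {
  df <- read_records_csv(path)
  ephemeris_table(df$timestamp, df$solar_elevation_deg,
                  df$lunar_elevation_deg, df$fraction_illuminated)
}

#' Read and write JSON ledgers
#'
#' Provenance and ground-truth ledgers (seeds, injected parameters, stage
#' record counts, config hashes) as JSON.
#'
#' @param x A list.
#' @param path JSON file path.
#' @return The path (write) or a list (read).
#' @export
write_ledger_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ledger_json
#' @export
read_ledger_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# md5 of the canonical JSON serialisation, used to stamp outputs
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a generated campaign to a directory of text tables
#'
#' Emits the layout consumed by [run_pipeline()]: `records.csv`,
#' `ephemeris_<location>.csv`, per-instrument `frames_<i>.csv` (counts),
#' `frame_meta_<i>.csv`, `darks_<i>.csv` + `dark_meta_<i>.csv`, `cf_<i>.csv`,
#' `lines_<i>.csv`, and `ground_truth.json`.
#'
#' @param camp A `sky_campaign`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(camp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_records_csv(camp$records, file.path(dir, "records.csv"))
  for (loc in names(camp$ephemeris))
    write_ephemeris_csv(camp$ephemeris[[loc]],
                        file.path(dir, paste0("ephemeris_", loc, ".csv")))
  for (ins in names(camp$cf)) {
    cf <- camp$cf[[ins]]
    utils::write.csv(
      data.frame(wavelength_nm = fmt17(cf$wavelength_nm),
                 factor = fmt17(cf$factors)),
      file.path(dir, paste0("cf_", ins, ".csv")), row.names = FALSE,
      quote = FALSE)
    ids <- camp$records$record_id[camp$records$instrument_id == ins]
    if (length(ids)) {
      write_spectra_csv(lapply(camp$frames[ids], `[[`, "counts"),
                        file.path(dir, paste0("frames_", ins, ".csv")))
      meta <- camp$records[match(ids, camp$records$record_id),
                           c("record_id", "integration_time_s",
                             "board_temp_C")]
      utils::write.csv(meta, file.path(dir, paste0("frame_meta_", ins,
                                                   ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    lib <- camp$dark_libs[[ins]]
    dk <- lapply(lib$frames, function(f) f$dark_counts)
    names(dk) <- sprintf("d%03d", seq_along(dk))
    write_spectra_csv(dk, file.path(dir, paste0("darks_", ins, ".csv")))
    utils::write.csv(
      data.frame(id = names(dk),
                 integration_time_s =
                   vapply(lib$frames, `[[`, 0, "integration_time_s"),
                 board_temp_C = vapply(lib$frames, `[[`, 0, "board_temp_C")),
      file.path(dir, paste0("dark_meta_", ins, ".csv")),
      row.names = FALSE, quote = FALSE)
    write_spectra_csv(list(lamp = camp$line_frames[[ins]]),
                      file.path(dir, paste0("lines_", ins, ".csv")))
  }
  gt <- camp$ground_truth
  gt$config_hash <- config_hash(camp$config)
  write_ledger_json(gt, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a campaign directory written by [write_campaign()]
#'
#' @param dir Campaign directory.
#' @param saturation_level ADC full scale used when rebuilding raw frames.
#' @return A `sky_campaign`-like list (without truth spectra or config).
#' @export
read_campaign <- function(dir, saturation_level = 65535) {
  need <- file.path(dir, "records.csv")
  if (!file.exists(need))
    stop("missing campaign file: ", need, call. = FALSE)
  records <- read_records_csv(need)
  frames <- list(); dark_libs <- list(); cf <- list(); line_frames <- list()
  for (ins in unique(records$instrument_id)) {
    fpath <- file.path(dir, paste0("frames_", ins, ".csv"))
    counts <- read_spectra_csv(fpath, units = "counts")
    meta <- utils::read.csv(file.path(dir, paste0("frame_meta_", ins,
                                                  ".csv")))
    for (k in seq_along(counts)) {
      id <- names(counts)[k]
      m <- meta[match(id, meta$record_id), ]
      frames[[id]] <- raw_frame(counts[[k]], m$integration_time_s,
                                m$board_temp_C, instrument_id = ins,
                                saturation_level = saturation_level)
    }
    cft <- utils::read.csv(file.path(dir, paste0("cf_", ins, ".csv")))
    cf[[ins]] <- correction_factors(cft$wavelength_nm, cft$factor)
    dk <- read_spectra_csv(file.path(dir, paste0("darks_", ins, ".csv")),
                           units = "counts")
    dmeta <- utils::read.csv(file.path(dir, paste0("dark_meta_", ins,
                                                   ".csv")))
    dark_libs[[ins]] <- dark_library(lapply(seq_along(dk), function(k) {
      m <- dmeta[match(names(dk)[k], dmeta$id), ]
      dark_frame(m$integration_time_s, m$board_temp_C, dk[[k]])
    }))
    line_frames[[ins]] <- read_spectra_csv(
      file.path(dir, paste0("lines_", ins, ".csv")), units = "counts")[[1]]
  }
  eph <- list()
  for (loc in unique(records$location_id))
    eph[[loc]] <- read_ephemeris_csv(
      file.path(dir, paste0("ephemeris_", loc, ".csv")))
  gt_path <- file.path(dir, "ground_truth.json")
  list(records = records, frames = frames, dark_libs = dark_libs, cf = cf,
       line_frames = line_frames, ephemeris = eph,
       ground_truth = if (file.exists(gt_path)) read_ledger_json(gt_path))
}
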