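#' Ephemeris tables
#'
#' Time-stamped solar and lunar geometry used to index every measurement:
#' solar elevation, lunar elevation (true, unrefracted, degrees) and the
#' fraction of the moon illuminated.
#'
#' @param timestamp POSIXct vector (UTC), strictly increasing.
#' @param solar_elevation_deg,lunar_elevation_deg Elevations in [-90, 90].
#' @param fraction_illuminated Fraction of the lunar disc lit, in [0, 1].
#' @return An `ephemeris_table` (a data frame).
#' @export
ephemeris_table <- function(timestamp, solar_elevation_deg,
                            lunar_elevation_deg, fraction_illuminated) {
  stopifnot(inherits(timestamp, "POSIXct"))
  if (any(diff(as.numeric(timestamp)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(abs(solar_elevation_deg) > 90) || any(abs(lunar_elevation_deg) > 90))
    stop("elevations must lie within [-90, 90]", call. = FALSE)
  if (any(fraction_illuminated < 0 | fraction_illuminated > 1))
    stop("fraction illuminated must lie within [0, 1]", call. = FALSE)
  structure(data.frame(timestamp = timestamp,
                       solar_elevation_deg = solar_elevation_deg,
                       lunar_elevation_deg = lunar_elevation_deg,
                       fraction_illuminated = fraction_illuminated),
            class = c("ephemeris_table", "data.frame"))
}

#' Interpolate an ephemeris table at measurement times
#'
#' Linear interpolation of solar elevation, lunar elevation and lunar fraction
#' between the bracketing table rows. Times outside the table's span are an
#' error (no extrapolation).
#'
#' @param table An `ephemeris_table`.
#' @param t POSIXct vector of query times.
#' @return A data frame with `solar_elevation_deg`, `lunar_elevation_deg`,
#'   `fraction_illuminated`, one row per query time.
#' @export
interpolate_ephemeris <- function(table, t) {
  stopifnot(inherits(table, "ephemeris_table"), inherits(t, "POSIXct"))
  tn <- as.numeric(t); rn <- as.numeric(table$timestamp)
  if (any(tn < rn[1] | tn > rn[length(rn)]))
    stop("query time outside the ephemeris table's span", call. = FALSE)
  data.frame(
    solar_elevation_deg = stats::approx(rn, table$solar_elevation_deg, tn)$y,
    lunar_elevation_deg = stats::approx(rn, table$lunar_elevation_deg, tn)$y,
    fraction_illuminated = stats::approx(rn, table$fraction_illuminated, tn)$y)
}

#' Classify solar elevation into illumination regimes
#'
#' Day (`theta_s >= 0`), civil twilight (`-6 <= theta_s < 0`), nautical
#' twilight (`-12 <= theta_s < -6`), astronomical twilight
#' (`-18 <= theta_s < -12`) and night (`theta_s < -18`). The boundaries are
#' assigned half-open so that every elevation maps to exactly one regime.
#'
#' @param theta_s Solar elevation(s) in degrees, within [-90, 90].
#' @return Factor with levels day, civil, nautical, astronomical, night.
#' @export
classify_regime <- function(theta_s) {
  if (any(abs(theta_s) > 90))
    stop("solar elevation outside [-90, 90]", call. = FALSE)
  cut(theta_s, breaks = c(-90.1, -18, -12, -6, 0, 90.1),
      labels = c("night", "astronomical", "nautical", "civil", "day"),
      right = FALSE)
}

#' Lunar-phase filter
#'
#' Restricts rural records to lunar illuminated fractions strictly below
#' `max_fraction` (default 0.3); city records are kept regardless of lunar
#' phase, since urban light pollution dominates moonlight there.
#'
#' @param records Data frame with columns `location_id` and
#'   `fraction_illuminated`.
#' @param max_fraction Strict upper bound for rural records; default 0.3.
#' @return The filtered data frame.
#' @export
lunar_filter <- function(records, max_fraction = 0.3) {
  keep <- records$location_id != "rural" |
    records$fraction_illuminated < max_fraction
  records[keep, , drop = FALSE]
}

#' Label records as dawn or dusk sequences
#'
#' Uses the sign of the finite-difference rate of change of solar elevation in
#' time within each contiguous session: decreasing elevation is dusk,
#' increasing is dawn. A zero difference inherits the preceding trend
#' (defaulting to dusk at the start of a session).
#'
#' @param records Data frame with `timestamp`, `solar_elevation_deg` and
#'   optionally `session_id` (one session assumed if absent).
#' @return The data frame with a `sequence` column (`"dawn"`/`"dusk"`).
#' @export
assign_sequence <- function(records) {
  if (is.null(records$session_id)) records$session_id <- 1L
  records$sequence <- NA_character_
  for (sid in unique(records$session_id)) {
    i <- which(records$session_id == sid)
    i <- i[order(records$timestamp[i])]
    el <- records$solar_elevation_deg[i]
    lab <- character(length(i))
    prev <- "dusk"
    d <- c(diff(el), 0)
    d[length(d)] <- if (length(d) > 1) d[length(d) - 1] else 0
    for (k in seq_along(i)) {
      lab[k] <- if (d[k] < 0) "dusk" else if (d[k] > 0) "dawn" else prev
      prev <- lab[k]
    }
    records$sequence[i] <- lab
  }
  records
}

#' Bin records by solar elevation
#'
#' Half-open bins `[k*width, (k+1)*width)` with edges at integer multiples of
#' the width, labelled by their centres. Standard widths are 1, 2 and 5
#' degrees.
#'
#' @param theta_s Solar elevations in degrees.
#' @param width_deg Bin width in degrees (> 0).
#' @return A data frame with `bin_center` and `bin_index` per input value.
#' @export
bin_by_elevation <- function(theta_s, width_deg = 2) {
  stopifnot(width_deg > 0)
  k <- floor(theta_s / width_deg)
  data.frame(bin_center = (k + 0.5) * width_deg, bin_index = k)
}
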