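# Survey tables: reading, validation, writing, and raw-data summaries.

#' The five recognised soil-source categories
#'
#' Order matters only for reporting; it matches the conventional indexing
#' k = 1..5: sidewalk cracks, small garden areas, parks, plant pots, tree pits.
#'
#' @return Character vector of the five category names.
#' @export
soil_types <- function() {
  c("sidewalk_crack", "garden", "park", "plant_pot", "tree_pit")
}

#' Read and validate a soil survey table
#'
#' Reads a comma-separated survey (UTF-8, `.` decimal) and returns a
#' validated survey `data.frame`. Locations may be given either as
#' `lon`/`lat` columns (converted with [to_polar()], which requires `origin`)
#' or directly as `r_km`/`bearing_deg`. Row order is preserved.
#'
#' Validation enforces: `pb_mg_kg` present and strictly positive, `soil_type`
#' one of [soil_types()], and positive distance from the source. `sn_mg_kg`
#' (tin) is optional and may contain missing values.
#'
#' @param path path to a CSV file with a header row.
#' @param origin optional numeric `c(lon, lat)` of the source; required when
#'   the file carries geographic rather than polar coordinates.
#' @param col_map optional named character vector mapping the canonical
#'   column names to the file's headers, e.g. `c(pb_mg_kg = "Pb")`.
#' @return A `data.frame` of class `plume_survey` with columns `sample_id`,
#'   `r_km`, `bearing_deg`, `soil_type`, `pb_mg_kg`, `sn_mg_kg`.
#' @seealso [write_survey()], [summarize_survey()]
#' @export
read_survey <- function(path, origin = NULL, col_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  if (!"pb_mg_kg" %in% names(raw)) {
    stop("survey is missing required column 'pb_mg_kg'", call. = FALSE)
  }
  if (!"soil_type" %in% names(raw)) {
    stop("survey is missing required column 'soil_type'", call. = FALSE)
  }
  has_polar <- all(c("r_km", "bearing_deg") %in% names(raw))
  has_geo <- all(c("lon", "lat") %in% names(raw))
  if (!has_polar && !has_geo) {
    stop("survey needs either 'r_km'+'bearing_deg' or 'lon'+'lat' columns",
         call. = FALSE)
  }
  if (!has_polar) {
    if (is.null(origin) || length(origin) != 2) {
      stop("'origin' = c(lon, lat) is required to convert lon/lat columns",
           call. = FALSE)
    }
    pol <- to_polar(raw$lon, raw$lat, origin[1], origin[2])
    raw$r_km <- pol$r_km
    raw$bearing_deg <- pol$bearing_deg
  }
  if (!"sample_id" %in% names(raw)) raw$sample_id <- as.character(seq_len(nrow(raw)))
  if (!"sn_mg_kg" %in% names(raw)) raw$sn_mg_kg <- NA_real_
  out <- raw[, c("sample_id", "r_km", "bearing_deg", "soil_type",
                 "pb_mg_kg", "sn_mg_kg")]
  out$sample_id <- as.character(out$sample_id)
  validate_survey(out)
  class(out) <- c("plume_survey", "data.frame")
  out
}

#' Validate a survey data.frame
#'
#' Checks the invariants required by the model: positive Pb, recognised soil
#' types, positive distances, bearings reducible to `[0, 360)`.
#'
#' @param samples a survey `data.frame` (see [read_survey()] for columns).
#' @return `samples`, invisibly, after normalising bearings to `[0, 360)`.
#' @export
validate_survey <- function(samples) {
  need <- c("r_km", "bearing_deg", "soil_type", "pb_mg_kg")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("survey is missing required column(s): ",
         paste0("'", miss, "'", collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) == 0) stop("survey has no rows", call. = FALSE)
  bad_pb <- which(!is.finite(samples$pb_mg_kg) | samples$pb_mg_kg <= 0)
  if (length(bad_pb)) {
    stop("non-positive or missing pb_mg_kg in row(s): ",
         paste(bad_pb, collapse = ", "), call. = FALSE)
  }
  bad_type <- which(!samples$soil_type %in% soil_types())
  if (length(bad_type)) {
    stop("unknown soil_type in row(s) ", paste(bad_type, collapse = ", "),
         "; allowed values: ", paste(soil_types(), collapse = ", "),
         call. = FALSE)
  }
  bad_r <- which(!is.finite(samples$r_km) | samples$r_km <= 0)
  if (length(bad_r)) {
    stop("non-positive distance r_km in row(s): ",
         paste(bad_r, collapse = ", "), call. = FALSE)
  }
  invisible(samples)
}

#' Write a survey table to CSV
#'
#' The written file round-trips through [read_survey()] with identical values
#' and row order.
#'
#' @param samples a survey `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(samples, path) {
  validate_survey(samples)
  utils::write.csv(
    samples[, c("sample_id", "r_km", "bearing_deg", "soil_type",
                "pb_mg_kg", "sn_mg_kg")],
    path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Raw-scale summary of a survey
#'
#' Arithmetic summaries on the measured mg/kg scale: overall mean and median,
#' per-soil-type means, in/out-of-sector means, and counts of samples
#' strictly exceeding a threshold, split by sector membership. Exceedance is
#' strict (`>`) because the reference value is a recommended maximum.
#'
#' @param samples a survey `data.frame`.
#' @param sector a [plume_sector()]; default 260--310 degrees.
#' @param threshold exceedance threshold in mg/kg. The default 300 mg/kg is
#'   the French health-authority recommendation for soil in public areas.
#' @return A list of class `survey_summary` with elements `n_total`,
#'   `mean_pb`, `median_pb`, `mean_by_type`, `n_by_type`, `mean_inside_plume`,
#'   `mean_outside_plume`, `n_inside`, `n_outside`, `n_exceeding_threshold`,
#'   `n_exceeding_inside`, `n_exceeding_outside`, `threshold`.
#' @export
summarize_survey <- function(samples, sector = plume_sector(),
                             threshold = 300) {
  validate_survey(samples)
  inside <- in_sector(samples$bearing_deg, sector)
  exceed <- samples$pb_mg_kg > threshold
  by_type <- tapply(samples$pb_mg_kg, factor(samples$soil_type, soil_types()),
                    mean)
  structure(list(
    n_total = nrow(samples),
    mean_pb = mean(samples$pb_mg_kg),
    median_pb = stats::median(samples$pb_mg_kg),
    mean_by_type = by_type,
    n_by_type = table(factor(samples$soil_type, soil_types())),
    mean_inside_plume = if (any(inside)) mean(samples$pb_mg_kg[inside]) else NA_real_,
    mean_outside_plume = if (any(!inside)) mean(samples$pb_mg_kg[!inside]) else NA_real_,
    n_inside = sum(inside),
    n_outside = sum(!inside),
    n_exceeding_threshold = sum(exceed),
    n_exceeding_inside = sum(exceed & inside),
    n_exceeding_outside = sum(exceed & !inside),
    threshold = threshold
  ), class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("Soil survey: %d samples\n", x$n_total))
  cat(sprintf("  Pb mean %.0f mg/kg, median %.0f mg/kg\n",
              x$mean_pb, x$median_pb))
  cat(sprintf("  inside plume sector: n=%d, mean %.0f mg/kg\n",
              x$n_inside, x$mean_inside_plume))
  cat(sprintf("  outside:             n=%d, mean %.0f mg/kg\n",
              x$n_outside, x$mean_outside_plume))
  cat(sprintf("  > %g mg/kg: %d samples (%d inside / %d outside)\n",
              x$threshold, x$n_exceeding_threshold,
              x$n_exceeding_inside, x$n_exceeding_outside))
  mt <- x$mean_by_type[!is.na(x$mean_by_type)]
  cat("  mean by soil type (mg/kg):\n")
  for (nm in names(mt)) {
    cat(sprintf("    %-15s %6.0f  (n=%d)\n", nm, mt[[nm]],
                as.integer(x$n_by_type[[nm]])))
  }
  invisible(x)
}

#' Recalibrated tin-to-lead mass ratio at high lead concentrations
#'
#' Handheld-XRF tin readings overestimate true concentrations by a known
#' slope factor (1.6 against ICP-MS digests); dividing by that slope
#' recalibrates them. The ratio `(sn / xrf_slope) / pb` is averaged over
#' samples with a tin value and Pb at or above `pb_min`, where the
#' fire-related Sn/Pb signature is detectable above background.
#'
#' @param samples a survey `data.frame` with an `sn_mg_kg` column.
#' @param pb_min minimum Pb concentration (mg/kg) for a sample to qualify;
#'   default 1000.
#' @param xrf_slope XRF-vs-ICPMS calibration slope for Sn; default 1.6.
#' @return Mean recalibrated Sn/Pb mass ratio (dimensionless proportion).
#' @export
sn_recalibrate_ratio <- function(samples, pb_min = 1000, xrf_slope = 1.6) {
  validate_survey(samples)
  ok <- !is.na(samples$sn_mg_kg) & samples$pb_mg_kg >= pb_min
  if (!any(ok)) {
    stop("no sample has a tin value and pb_mg_kg >= ", pb_min, call. = FALSE)
  }
  mean((samples$sn_mg_kg[ok] / xrf_slope) / samples$pb_mg_kg[ok])
}
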