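#' Survey CSV schemas
#'
#' Column contracts for the four survey tables. Each schema lists the
#' mandatory columns and their readr column types; extra columns are
#' preserved. Month labels are always derived from `date`, never read from
#' the file.
#'
#' @format A named list with elements `reference_isotopes`,
#'   `consumer_isotopes`, `tows`, `fish`.
#' @export
survey_schemas <- list(
  reference_isotopes = list(
    cols = c(sample_id = "c", taxon = "c", habitat = "c", date = "D",
             d13C_bulk = "d", d15N = "d", CN_bulk = "d", pooled_n = "i")
  ),
  consumer_isotopes = list(
    cols = c(sample_id = "c", stage = "c", habitat = "c", date = "D",
             d13C_bulk = "d", d15N = "d", CN_bulk = "d", pooled_n = "i")
  ),
  tows = list(
    cols = c(tow_id = "c", habitat = "c", date = "D",
             net_diameter_m = "d", speed_m_s = "d", duration_s = "d",
             n_nets = "i", dry_mass_mg = "d", larval_count = "i")
  ),
  fish = list(
    cols = c(fish_id = "c", habitat = "c", date = "D", stage = "c",
             standard_length_mm = "d", wet_mass_g = "d", age0 = "l")
  )
)

fail_rows <- function(ok, what) {
  if (!all(ok)) {
    stop(what, " in row(s): ",
         paste(utils::head(which(!ok), 10), collapse = ", "),
         if (sum(!ok) > 10) " ..." else "", call. = FALSE)
  }
}

validate_survey <- function(records, schema) {
  hab_ok <- is.na(records$habitat) | records$habitat %in% HABITATS
  fail_rows(hab_ok, "unknown habitat label")
  switch(schema,
    reference_isotopes = {
      fail_rows(records$taxon %in% REFERENCE_TAXA, "unknown reference taxon")
      fail_rows(is.finite(records$CN_bulk) & records$CN_bulk > 0,
                "nonpositive C:N ratio")
      fail_rows(is.na(records$pooled_n) | records$pooled_n >= 1,
                "pooled_n below 1")
      warn_d13C_range(records$d13C_bulk)
    },
    consumer_isotopes = {
      fail_rows(records$stage %in% CONSUMER_STAGES, "unknown consumer stage")
      fail_rows(is.finite(records$CN_bulk) & records$CN_bulk > 0,
                "nonpositive C:N ratio")
      fail_rows(is.na(records$pooled_n) | records$pooled_n >= 1,
                "pooled_n below 1")
      warn_d13C_range(records$d13C_bulk)
    },
    tows = {
      fail_rows(records$speed_m_s > 0, "nonpositive tow speed")
      fail_rows(records$duration_s > 0, "nonpositive tow duration")
      fail_rows(records$net_diameter_m > 0, "nonpositive net diameter")
      fail_rows(records$n_nets >= 1, "n_nets below 1")
      fail_rows(records$dry_mass_mg >= 0, "negative dry mass")
      fail_rows(records$larval_count >= 0, "negative larval count")
    },
    fish = {
      fail_rows(records$stage %in% CONSUMER_STAGES, "unknown fish stage")
      fail_rows(records$standard_length_mm > 0, "nonpositive standard length")
      juv <- records$stage == "juvenile"
      fail_rows(!juv | !is.na(records$wet_mass_g),
                "juvenile record missing wet mass")
    }
  )
  invisible(records)
}

warn_d13C_range <- function(d13C) {
  oob <- is.finite(d13C) & (d13C < -40 | d13C > -10)
  if (any(oob)) {
    warning(sum(oob), " delta-13C value(s) outside the typical [-40, -10] ",
            "per-mil range", call. = FALSE)
  }
  invisible(NULL)
}

#' Read and validate a survey CSV
#'
#' Reads one of the four survey tables, enforcing the header contract of
#' [survey_schemas] and validating rows (enums, positivity, juvenile mass
#' present). Validation failures name the offending rows. A `month` factor
#' column (June-September ordering) is derived from `date`.
#'
#' @param path CSV file path.
#' @param schema one of `"reference_isotopes"`, `"consumer_isotopes"`,
#'   `"tows"`, `"fish"`.
#' @return A validated tibble.
#' @export
read_survey_csv <- function(path, schema = names(survey_schemas)) {
  schema <- match.arg(schema)
  col_spec <- survey_schemas[[schema]]$cols
  records <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  missing <- setdiff(names(col_spec), names(records))
  if (length(missing)) {
    stop("schema '", schema, "': missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parse1 <- function(x, type, col) {
    out <- switch(type,
      c = x,
      d = suppressWarnings(as.numeric(x)),
      i = suppressWarnings(as.integer(x)),
      D = as.Date(x),
      l = as.logical(x))
    bad <- !is.na(x) & is.na(out)
    fail_rows(!bad, paste0("unparseable ", col, " value"))
    out
  }
  for (col in names(col_spec)) {
    records[[col]] <- parse1(records[[col]], col_spec[[col]], col)
  }
  records <- tibble::as_tibble(records)
  if (nrow(records)) validate_survey(records, schema)
  records$month <- if (schema == "tows") tow_month(records$date)
                   else month_label(records$date)
  records
}

#' Write a survey table to CSV
#'
#' Inverse of [read_survey_csv()]: writes the schema columns (dates in ISO
#' format) so that a write-then-read round trip is the identity. The
#' derived `month` column is not written.
#'
#' @param records a survey tibble.
#' @param path output CSV path.
#' @param schema schema name, as in [read_survey_csv()].
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(records, path, schema = names(survey_schemas)) {
  schema <- match.arg(schema)
  keep <- intersect(c(names(survey_schemas[[schema]]$cols),
                      setdiff(names(records), "month")), names(records))
  readr::write_csv(records[keep], path)
  invisible(path)
}

#' Month label from date
#'
#' Calendar-month factor with the field-season ordering June < July <
#' August < September. Dates outside those months give `NA` with a warning.
#'
#' @param date a `Date` vector.
#' @return An ordered-level factor.
#' @export
month_label <- function(date) {
  lab <- months(date)
  out <- factor(lab, levels = MONTHS)
  if (any(!is.na(date) & is.na(out))) {
    warning("date(s) outside the June-September field season", call. = FALSE)
  }
  out
}

#' Tow month grouping
#'
#' Groups plankton-tow dates into the analysis months: tows on or before
#' July 1 are "June", later tows through August 1 are "July". (The field
#' protocol's June cutoff is interpreted as the end of the first sampling
#' block, i.e. on or before July 1.) Later dates give `NA` with a warning.
#'
#' @param date a `Date` vector.
#' @return A factor with levels June, July.
#' @export
tow_month <- function(date) {
  yr <- as.integer(format(date, "%Y"))
  june_end <- as.Date(sprintf("%d-07-01", yr))
  july_end <- as.Date(sprintf("%d-08-01", yr))
  out <- ifelse(date <= june_end, "June",
                ifelse(date <= july_end, "July", NA_character_))
  if (any(!is.na(date) & is.na(out))) {
    warning("tow date(s) after August 1 fall outside the June/July ",
            "grouping", call. = FALSE)
  }
  factor(out, levels = c("June", "July"))
}

#' Volume of water filtered by a plankton tow
#'
#' n_nets * pi * (diameter / 2)^2 * speed * duration. Paired-net contents
#' are combined in the field, so the filtered volume scales with the
#' number of nets.
#'
#' @param tows a tows tibble (see [survey_schemas]).
#' @return Volume in cubic metres, one value per tow.
#' @examples
#' # protocol defaults: 2 nets, 0.75 m diameter, 0.6 m/s, 120 s -> ~63.6 m^3
#' @export
tow_volume <- function(tows) {
  validate_survey(tows, "tows")
  tows$n_nets * pi * (tows$net_diameter_m / 2)^2 *
    tows$speed_m_s * tows$duration_s
}

#' Zooplankton density from a tow
#'
#' Retained dry mass divided by the filtered volume, mg per cubic metre.
#' An optional carbon-fraction multiplier converts dry mass to carbon mass
#' (default 1, i.e. plain dry mass).
#'
#' @inheritParams tow_volume
#' @param carbon_fraction multiplier applied to dry mass (default 1).
#' @return Density in mg (dry mass or carbon) per cubic metre, per tow.
#' @export
zooplankton_density <- function(tows, carbon_fraction = 1) {
  carbon_fraction * tows$dry_mass_mg / tow_volume(tows)
}

#' Pooled larval density per habitat
#'
#' Larval density (larvae per cubic metre) pooled over a window of tows:
#' total larval count divided by total filtered volume, per habitat. The
#' field protocol pools three to five tows over two consecutive sampling
#' days; a count outside 3-5 per habitat triggers a warning but is still
#' computed.
#'
#' @inheritParams tow_volume
#' @param window optional `Date` vector of length 2 (inclusive window) used
#'   to subset `tows` before pooling.
#' @return A tibble with `habitat`, `n_tows`, `total_count`,
#'   `total_volume_m3`, `density_per_m3`. Habitats with no tows in the
#'   window are absent.
#' @export
larval_density <- function(tows, window = NULL) {
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    tows <- tows[tows$date >= min(window) & tows$date <= max(window), ]
  }
  if (nrow(tows) == 0) {
    return(tibble::tibble(habitat = character(), n_tows = integer(),
                          total_count = integer(), total_volume_m3 = double(),
                          density_per_m3 = double()))
  }
  vol <- tow_volume(tows)
  out <- tows |>
    dplyr::mutate(.vol = vol) |>
    dplyr::group_by(.data$habitat) |>
    dplyr::summarise(
      n_tows = dplyr::n(),
      total_count = sum(.data$larval_count),
      total_volume_m3 = sum(.data$.vol),
      density_per_m3 = sum(.data$larval_count) / sum(.data$.vol),
      .groups = "drop"
    )
  if (any(out$n_tows < 3 | out$n_tows > 5)) {
    warning("habitat(s) with fewer than 3 or more than 5 pooled tows; ",
            "density computed anyway", call. = FALSE)
  }
  out
}
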