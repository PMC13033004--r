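#' Published summary statistics from the 2014 Ashby Lake survey
#'
#' The field-season summary table the synthetic generator's defaults
#' emulate: mean standard length (mm) and wet body mass (g) with standard
#' errors and sample sizes of pumpkinseed larvae (June, July) and age-0
#' juveniles (August, September) per lake habitat. Larval mass could not
#' be measured in the field, so mass cells are empty for June and July.
#'
#' @return A tibble: `habitat`, `month`, `stage`, `n`, `mean_sl_mm`,
#'   `sem_sl_mm`, `mean_mass_g`, `sem_mass_g`.
#' @export
published_table1 <- function() {
  path <- system.file("extdata", "ashby2014_table1.csv", package = "isojuv",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    habitat = "c", month = "c", stage = "c", n = "i",
                    mean_sl_mm = "d", sem_sl_mm = "d",
                    mean_mass_g = "d", sem_mass_g = "d"))
}

#' Other published summary values from the 2014 Ashby Lake survey
#'
#' Headline summary values reported for the field season, used to
#' parameterize the synthetic scenario and to reproduce the derived
#' ratios: monthly all-habitat zooplankton density means, monthly mean
#' %-planktonic tissue fractions, the September ANCOVA-adjusted mean
#' masses, the September pelagic median %-planktonic, and the larval
#' littoral:pelagic peak-density ratio.
#'
#' @return A named numeric vector.
#' @export
published_values <- function() {
  path <- system.file("extdata", "ashby2014_reported.csv", package = "isojuv",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(quantity = "c", value = "d"))
  stats::setNames(tab$value, tab$quantity)
}

#' Derived headline ratios from published means
#'
#' Recomputes, by arithmetic on the published summary statistics, the
#' study's headline contrasts: the percent excess of pelagic over littoral
#' September mean standard length and mean mass, the percent excess of
#' littoral over pelagic September ANCOVA-adjusted mass, and the
#' June:July zooplankton density factor.
#'
#' @param table1 tibble from [published_table1()].
#' @param values named vector from [published_values()].
#' @return A named numeric vector with elements
#'   `sl_excess_pelagic_sept_pct`, `mass_excess_pelagic_sept_pct`,
#'   `adj_mass_excess_littoral_pct`, `june_july_density_factor`.
#' @export
headline_ratios_from_published <- function(table1 = published_table1(),
                                           values = published_values()) {
  sept <- table1[table1$month == "September", ]
  sl_l <- sept$mean_sl_mm[sept$habitat == "littoral"]
  sl_p <- sept$mean_sl_mm[sept$habitat == "pelagic"]
  m_l <- sept$mean_mass_g[sept$habitat == "littoral"]
  m_p <- sept$mean_mass_g[sept$habitat == "pelagic"]
  c(
    sl_excess_pelagic_sept_pct = 100 * (sl_p - sl_l) / sl_l,
    mass_excess_pelagic_sept_pct = 100 * (m_p - m_l) / m_l,
    adj_mass_excess_littoral_pct =
      100 * (values[["adj_mass_littoral_g"]] - values[["adj_mass_pelagic_g"]]) /
        values[["adj_mass_pelagic_g"]],
    june_july_density_factor =
      values[["density_june_mg_m3"]] / values[["density_july_mg_m3"]]
  )
}
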