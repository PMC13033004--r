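#' Synthetic survey scenario
#'
#' Full parameterization of the forward model that generates the four
#' survey tables (reference isotopes, consumer isotopes, plankton tows,
#' fish morphometrics) with known ground truth. Defaults encode the 2014
#' Ashby Lake pumpkinseed study conditions that the package emulates:
#' Table-1 standard-length/mass means and sample sizes, 13 June and 19
#' July tows per habitat with all-habitat mean densities 4.73 and 1.13
#' mg/m^3, a littoral larval-density peak seven times the pelagic one,
#' roughly 10 per-mil baseline separation between the planktonic (mussel)
#' and benthic (snail) end-members, and per-stratum true %-planktonic
#' values whose monthly all-habitat means are 90.6, 80.3, 75.5 and 76.6.
#'
#' @param seed integer seed; every generator draws deterministically from
#'   it. Changing the seed changes draws but never truth parameters.
#' @param ... named overrides of any default listed below (unknown names
#'   are an error).
#' @return A list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    year = 2014L,
    # true fraction of consumer tissue from the planktonic pathway,
    # per habitat x month; monthly all-habitat means 0.906/0.803/0.755/0.766
    true_planktonic = tibble::tibble(
      habitat = rep(HABITATS, times = 4),
      month = rep(MONTHS, each = 3),
      p = c(0.93, 0.87, 0.92,    # June
            0.74, 0.80, 0.87,    # July
            0.68, 0.735, 0.85,   # August
            0.72, 0.68, 0.90)    # September
    ),
    # lipid-free baseline means/SDs (per mil); mussel-snail separation 10,
    # mussel-zooplankton separation 1 => ten-fold proxy ratio
    baselines = tibble::tibble(
      taxon = c("mussel", "snail", "zooplankton"),
      d13C_mean = c(-28, -18, -27),
      d13C_sd = c(0.8, 0.8, 0.8),
      d15N_mean = c(5.5, 2.5, 5.7),
      d15N_sd = c(0.6, 0.6, 0.6)
    ),
    n_ref = 15L,                     # reference samples per taxon x habitat
    invert_CN_meanlog = log(4.5),    # invertebrate C:N (lognormal)
    invert_CN_sdlog = 0.08,
    consumers_per_stratum = 200L,
    consumer_sigma = 0.5,            # per-mil SD of lipid-free consumer d13C
    fish_CN_meanlog = log(4.2),      # fish C:N (lognormal, truncated)
    fish_CN_sdlog = 0.12,
    CN_min = 3.2,                    # redraw below the fish-correction domain
    d15N_fractionation = 3.4,        # trophic enrichment per level (unused by mixing)
    d15N_sigma = 0.4,
    # zooplankton density means, mg dry mass / m^3 (all-habitat means:
    # June 4.73, July 1.13; pelagic highest)
    density_mean = tibble::tibble(
      habitat = rep(HABITATS, times = 2),
      month = rep(c("June", "July"), each = 3),
      density = c(3.5, 3.7, 7.0, 0.7, 0.9, 1.8)
    ),
    density_cv = 0.4,
    # paired-day tow schedule: 13 June, 19 July tows per habitat
    tow_dates_june = c(rep(c("-05-29", "-05-30", "-06-09", "-06-10",
                             "-06-24", "-06-25"), each = 2), "-07-01"),
    tow_dates_july = c(rep(c("-07-08", "-07-09", "-07-15", "-07-16",
                             "-07-22", "-07-23", "-07-29", "-07-30"),
                           each = 2), rep("-08-01", 3)),
    net_diameter_m = 0.75, speed_m_s = 0.6, duration_s = 120, n_nets = 2L,
    # larval density: Gaussian pulse peaking in late June, littoral peak
    # seven times the pelagic/shoreline peaks
    larval_peak_date = "-06-25",
    larval_peak_sd_days = 8,
    larval_peak_density = c(littoral = 0.5, shoreline = 0.5 / 7,
                            pelagic = 0.5 / 7),
    # fish morphometrics: Table-1 means/sems/ns (SL in mm, mass in g)
    table1 = published_table1(),
    # mass-length allometry mass = a * SL^b; a is set per stratum so the
    # stratum mean mass matches Table 1 at the stratum mean SL. b is 3 as
    # baseline, steeper for August pelagic fish and shallower for
    # September shoreline fish (the habitat contrasts the condition
    # analysis is meant to detect)
    allometry_b = tibble::tibble(
      habitat = rep(HABITATS, times = 2),
      month = rep(c("August", "September"), each = 3),
      b = c(3.0, 3.0, 3.3, 3.0, 2.7, 3.0)
    ),
    mass_sdlog = 0.08,
    constants = lipid_constants()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown scenario parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sc <- utils::modifyList(defaults, overrides)
  stopifnot(all(sc$true_planktonic$p >= 0 & sc$true_planktonic$p <= 1),
            all(sc$baselines$d13C_sd >= 0), sc$consumer_sigma >= 0,
            sc$CN_min > sc$constants$L_c2 / sc$constants$L_c1)
  structure(sc, class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic survey scenario (seed ", x$seed, "):\n", sep = "")
  cat("  consumers:", x$consumers_per_stratum, "per stratum, sigma =",
      x$consumer_sigma, "per mil\n")
  cat("  baselines: mussel", x$baselines$d13C_mean[1], "/ snail",
      x$baselines$d13C_mean[2], "/ zooplankton",
      x$baselines$d13C_mean[3], "per mil d13C\n")
  cat("  tows:", length(x$tow_dates_june), "June +",
      length(x$tow_dates_july), "July per habitat\n")
  invisible(x)
}

scenario_date <- function(scenario, suffix) {
  as.Date(paste0(scenario$year, suffix))
}

mid_month_date <- function(scenario, month) {
  num <- match(month, MONTHS) + 5L
  as.Date(sprintf("%d-%02d-15", scenario$year, num))
}

#' Generate reference-taxon isotope samples
#'
#' Draws `n_ref` samples per taxon x habitat. Lipid-free delta-13C and
#' delta-15N are normal draws around the scenario baseline means; the
#' stored bulk delta-13C is obtained by inverting the invertebrate
#' mass-balance correction at each sample's drawn C:N, so applying
#' [lipid_correct_invert()] downstream recovers the lipid-free values
#' exactly.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A `reference_isotopes` tibble (see [survey_schemas]).
#' @export
generate_baselines <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed + 1L)
  grid <- expand.grid(taxon = scenario$baselines$taxon, habitat = HABITATS,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tx <- grid$taxon[i]
    bl <- scenario$baselines[scenario$baselines$taxon == tx, ]
    n <- scenario$n_ref
    d13C_free <- stats::rnorm(n, bl$d13C_mean, bl$d13C_sd)
    d15N <- stats::rnorm(n, bl$d15N_mean, bl$d15N_sd)
    CN <- stats::rlnorm(n, scenario$invert_CN_meanlog, scenario$invert_CN_sdlog)
    d13C_bulk <- d13C_free - scenario$constants$invert_D *
      (CN - scenario$constants$invert_CNex) / CN
    tibble::tibble(
      sample_id = sprintf("ref_%s_%s_%02d", tx, grid$habitat[i], seq_len(n)),
      taxon = tx, habitat = grid$habitat[i],
      date = scenario_date(scenario, "-06-15"),
      d13C_bulk = d13C_bulk, d15N = d15N, CN_bulk = CN,
      pooled_n = 1L
    )
  })
  out <- dplyr::bind_rows(rows)
  out$month <- month_label(out$date)
  out
}

#' Generate consumer isotope samples with hidden truth
#'
#' For each habitat x month stratum, draws lipid-free consumer delta-13C
#' as p * base1 + (1 - p) * base2 + N(0, sigma) where p is the stratum's
#' true planktonic fraction and base1/base2 are the scenario's mussel and
#' snail delta-13C means. Each fish's C:N is a truncated lognormal draw
#' (values below `CN_min` are redrawn; the count is attached as attribute
#' `n_redraws`), and the stored bulk delta-13C subtracts the exact fish
#' lipid correction at that C:N, so [lipid_correct_fish()] inverts it to
#' numerical precision. delta-15N carries a simulated trophic
#' fractionation offset that the mixing model never uses.
#'
#' @inheritParams generate_baselines
#' @return A list: `consumers` (a `consumer_isotopes` tibble) and `truth`
#'   (tibble habitat, month, true_planktonic, n).
#' @export
generate_consumers <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed + 2L)
  base1 <- scenario$baselines$d13C_mean[scenario$baselines$taxon == "mussel"]
  base2 <- scenario$baselines$d13C_mean[scenario$baselines$taxon == "snail"]
  base1_N <- scenario$baselines$d15N_mean[scenario$baselines$taxon == "mussel"]
  base2_N <- scenario$baselines$d15N_mean[scenario$baselines$taxon == "snail"]
  tp <- scenario$true_planktonic
  n_redraws <- 0L
  rows <- lapply(seq_len(nrow(tp)), function(i) {
    n <- scenario$consumers_per_stratum
    p <- tp$p[i]
    d13C_free <- p * base1 + (1 - p) * base2 +
      stats::rnorm(n, 0, scenario$consumer_sigma)
    CN <- stats::rlnorm(n, scenario$fish_CN_meanlog, scenario$fish_CN_sdlog)
    while (any(low <- CN < scenario$CN_min)) {
      n_redraws <<- n_redraws + sum(low)
      CN[low] <- stats::rlnorm(sum(low), scenario$fish_CN_meanlog,
                               scenario$fish_CN_sdlog)
    }
    d13C_bulk <- d13C_free - fish_lipid_correction(CN, scenario$constants)
    stage <- if (tp$month[i] %in% c("June", "July")) "larval" else "juvenile"
    pooled <- if (stage == "larval") 5L else 1L
    tibble::tibble(
      sample_id = sprintf("con_%s_%s_%03d", tp$habitat[i], tp$month[i],
                          seq_len(n)),
      stage = stage, habitat = tp$habitat[i],
      date = mid_month_date(scenario, tp$month[i]),
      d13C_bulk = d13C_bulk,
      d15N = p * base1_N + (1 - p) * base2_N + scenario$d15N_fractionation +
        stats::rnorm(n, 0, scenario$d15N_sigma),
      CN_bulk = CN,
      pooled_n = pooled
    )
  })
  consumers <- dplyr::bind_rows(rows)
  consumers$month <- month_label(consumers$date)
  truth <- tibble::tibble(habitat = tp$habitat, month = tp$month,
                          true_planktonic = tp$p,
                          n = scenario$consumers_per_stratum)
  attr(consumers, "n_redraws") <- n_redraws
  list(consumers = consumers, truth = truth)
}

#' Generate plankton-tow records
#'
#' One tow per scheduled date per habitat. Per-tow zooplankton density is
#' a lognormal draw whose mean equals the scenario's habitat x month
#' density; the stored dry mass is density times filtered volume, so
#' [zooplankton_density()] recovers the draws exactly. Larval counts are
#' Poisson with intensity following a Gaussian pulse over time that peaks
#' in late June, with the littoral peak seven times the pelagic one at the
#' defaults.
#'
#' @inheritParams generate_baselines
#' @return A `tows` tibble (see [survey_schemas]).
#' @export
generate_tows <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed + 3L)
  sdlog <- sqrt(log(1 + scenario$density_cv^2))
  peak <- scenario_date(scenario, scenario$larval_peak_date)
  vol1 <- scenario$n_nets * pi * (scenario$net_diameter_m / 2)^2 *
    scenario$speed_m_s * scenario$duration_s
  sched <- rbind(
    data.frame(month = "June", suffix = scenario$tow_dates_june),
    data.frame(month = "July", suffix = scenario$tow_dates_july)
  )
  rows <- lapply(HABITATS, function(h) {
    dates <- scenario_date(scenario, sched$suffix)
    mu <- scenario$density_mean$density[
      match(paste(h, sched$month),
            paste(scenario$density_mean$habitat, scenario$density_mean$month))]
    dens <- stats::rlnorm(length(dates), log(mu) - sdlog^2 / 2, sdlog)
    days <- as.numeric(dates - peak)
    lam <- scenario$larval_peak_density[[h]] *
      exp(-days^2 / (2 * scenario$larval_peak_sd_days^2))
    tibble::tibble(
      tow_id = sprintf("tow_%s_%02d", h, seq_along(dates)),
      habitat = h, date = dates,
      net_diameter_m = scenario$net_diameter_m,
      speed_m_s = scenario$speed_m_s,
      duration_s = scenario$duration_s,
      n_nets = scenario$n_nets,
      dry_mass_mg = dens * vol1,
      larval_count = stats::rpois(length(dates), lam * vol1)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$month <- tow_month(out$date)
  out
}

#' Generate fish morphometric records
#'
#' Standard lengths are normal draws per habitat x month stratum around
#' the Table-1 means (SD recovered as sem * sqrt(n)); sample sizes follow
#' Table 1. Juvenile wet mass follows mass = a * SL^b times mean-one
#' lognormal noise, with the exponent b habitat- and month-specific and
#' the coefficient a set so the stratum mean mass matches Table 1 at the
#' stratum mean length. Larvae (June, July) carry no mass.
#'
#' @inheritParams generate_baselines
#' @return A `fish` tibble (see [survey_schemas]).
#' @export
generate_fish <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed + 4L)
  t1 <- scenario$table1
  rows <- lapply(seq_len(nrow(t1)), function(i) {
    n <- t1$n[i]
    sl_sd <- t1$sem_sl_mm[i] * sqrt(n)
    sl <- stats::rnorm(n, t1$mean_sl_mm[i], sl_sd)
    while (any(bad <- sl <= 0)) {
      sl[bad] <- stats::rnorm(sum(bad), t1$mean_sl_mm[i], sl_sd)
    }
    juvenile <- !is.na(t1$mean_mass_g[i])
    mass <- rep(NA_real_, n)
    if (juvenile) {
      b <- scenario$allometry_b$b[
        scenario$allometry_b$habitat == t1$habitat[i] &
        scenario$allometry_b$month == t1$month[i]]
      a <- t1$mean_mass_g[i] / t1$mean_sl_mm[i]^b
      noise <- exp(stats::rnorm(n, -scenario$mass_sdlog^2 / 2,
                                scenario$mass_sdlog))
      mass <- a * sl^b * noise
    }
    tibble::tibble(
      fish_id = sprintf("fish_%s_%s_%03d", t1$habitat[i], t1$month[i],
                        seq_len(n)),
      habitat = t1$habitat[i],
      date = mid_month_date(scenario, t1$month[i]),
      stage = if (juvenile) "juvenile" else "larval",
      standard_length_mm = sl,
      wet_mass_g = mass,
      age0 = TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  out$month <- month_label(out$date)
  out
}

#' Generate the full synthetic survey
#'
#' Runs all four generators in a fixed order. Each generator reseeds
#' deterministically from the scenario seed, so every table is identical
#' whether generated alone or through this wrapper.
#'
#' @inheritParams generate_baselines
#' @return A list: `reference`, `consumers`, `tows`, `fish`, `truth`,
#'   `scenario`.
#' @export
generate_survey <- function(scenario = synthetic_scenario()) {
  con <- generate_consumers(scenario)
  list(
    reference = generate_baselines(scenario),
    consumers = con$consumers,
    tows = generate_tows(scenario),
    fish = generate_fish(scenario),
    truth = con$truth,
    scenario = scenario
  )
}

#' Write a synthetic survey to CSV files
#'
#' Writes the four survey tables plus a `truth.csv` sidecar with the true
#' per-stratum planktonic fractions to `dir`.
#'
#' @inheritParams generate_baselines
#' @param dir output directory (created if absent).
#' @return Named character vector of the file paths, invisibly.
#' @export
simulate_survey_csv <- function(scenario = synthetic_scenario(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  svy <- generate_survey(scenario)
  paths <- c(
    reference = file.path(dir, "reference_isotopes.csv"),
    consumers = file.path(dir, "consumer_isotopes.csv"),
    tows = file.path(dir, "tows.csv"),
    fish = file.path(dir, "fish.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_survey_csv(svy$reference, paths["reference"], "reference_isotopes")
  write_survey_csv(svy$consumers, paths["consumers"], "consumer_isotopes")
  write_survey_csv(svy$tows, paths["tows"], "tows")
  write_survey_csv(svy$fish, paths["fish"], "fish")
  readr::write_csv(svy$truth, paths["truth"])
  invisible(paths)
}
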