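test_that("the generator is deterministic under a fixed seed", {
  s1 <- generate_survey(synthetic_scenario(seed = 5))
  s2 <- generate_survey(synthetic_scenario(seed = 5))
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$consumers, s2$consumers)
  expect_identical(s1$tows, s2$tows)
  expect_identical(s1$fish, s2$fish)
  # changing only the seed changes draws but not truth parameters
  s3 <- generate_survey(synthetic_scenario(seed = 6))
  expect_false(identical(s1$consumers$d13C_bulk, s3$consumers$d13C_bulk))
  expect_identical(s1$truth, s3$truth)
})

test_that("zero-noise baselines collapse to their means after correction", {
  sc <- synthetic_scenario(seed = 5, baselines = tibble::tibble(
    taxon = c("mussel", "snail", "zooplankton"),
    d13C_mean = c(-28, -18, -27), d13C_sd = 0,
    d15N_mean = c(5.5, 2.5, 5.7), d15N_sd = 0
  ))
  ref <- generate_baselines(sc)
  sm <- summarize_baselines(ref)  # invertebrate correction inverts exactly
  expect_equal(sm$mean_d13C[sm$taxon == "mussel"], rep(-28, 3))
  expect_equal(sm$mean_d13C[sm$taxon == "snail"], rep(-18, 3))
  expect_equal(sm$se_d13C, rep(0, 9), tolerance = 1e-12)
})

test_that("baseline summaries recover generating means from large samples", {
  sc <- synthetic_scenario(seed = 8, n_ref = 500L)
  sm <- summarize_baselines(generate_baselines(sc))
  pooled <- tapply(rep(sm$mean_d13C, sm$n), rep(sm$taxon, sm$n), mean)
  for (tx in names(pooled)) {
    mu <- sc$baselines$d13C_mean[sc$baselines$taxon == tx]
    sd3 <- 3 * sc$baselines$d13C_sd[sc$baselines$taxon == tx] / sqrt(1500)
    expect_lt(abs(pooled[[tx]] - mu), sd3)
  }
})

test_that("noise-free consumers invert the mixing model exactly", {
  tp1 <- synthetic_scenario()$true_planktonic
  tp1$p <- 1
  sc1 <- synthetic_scenario(seed = 5, true_planktonic = tp1,
                            consumer_sigma = 0, consumers_per_stratum = 5L)
  con1 <- generate_consumers(sc1)$consumers
  b <- baseline_pair(-28, -18)
  est1 <- percent_planktonic(lipid_correct_fish(con1$d13C_bulk, con1$CN_bulk), b)
  expect_equal(est1, rep(100, nrow(con1)))
  tp2 <- tp1; tp2$p <- 0.75
  sc2 <- synthetic_scenario(seed = 5, true_planktonic = tp2,
                            consumer_sigma = 0, consumers_per_stratum = 5L)
  con2 <- generate_consumers(sc2)$consumers
  est2 <- percent_planktonic(lipid_correct_fish(con2$d13C_bulk, con2$CN_bulk), b)
  expect_equal(est2, rep(75, nrow(con2)))
})

test_that("mean planktonic fraction is recovered from noisy consumers", {
  tp <- synthetic_scenario()$true_planktonic
  tp$p <- 0.7
  sc <- synthetic_scenario(seed = 9, true_planktonic = tp)
  con <- generate_consumers(sc)$consumers
  b <- baseline_pair(-28, -18)
  est <- percent_planktonic(lipid_correct_fish(con$d13C_bulk, con$CN_bulk), b)
  # 12 strata x 200 consumers; truth 70%, sigma 0.5 per mil over a 10
  # per-mil baseline gap -> SE = 5 / sqrt(n) percentage points
  se <- 100 * sc$consumer_sigma / 10 / sqrt(length(est))
  expect_lt(abs(mean(est) - 70), 2 * se)
  expect_true(all(con$CN_bulk >= sc$CN_min))
})

test_that("tow generation reproduces the seasonal density decline and larval pulse", {
  ratios <- vapply(1:20, function(i) {
    tw <- generate_tows(synthetic_scenario(seed = 100 + i))
    dens <- zooplankton_density(tw)
    mean(dens[tw$month == "June"]) / mean(dens[tw$month == "July"])
  }, double(1))
  expect_equal(mean(ratios), 4.73 / 1.13, tolerance = 0.1)
  # littoral larval peak about seven times the pelagic peak
  lr <- vapply(1:20, function(i) {
    sc <- synthetic_scenario(seed = 200 + i)
    tw <- generate_tows(sc)
    peak <- as.Date("2014-06-25")
    ld <- larval_density(tw, window = c(peak - 1, peak))
    ld$density_per_m3[ld$habitat == "littoral"] /
      ld$density_per_m3[ld$habitat == "pelagic"]
  }, double(1))
  expect_equal(mean(lr), 7, tolerance = 0.15)
  # zero intensity gives zero counts
  sc0 <- synthetic_scenario(seed = 5, larval_peak_density = c(
    littoral = 0, shoreline = 0, pelagic = 0))
  expect_true(all(generate_tows(sc0)$larval_count == 0))
})

test_that("fish generation matches the published stratum means", {
  # noise-free: sample means equal the scenario means exactly
  t1 <- published_table1()
  t1z <- t1; t1z$sem_sl_mm <- 0
  scz <- synthetic_scenario(seed = 5, table1 = t1z, mass_sdlog = 0)
  fz <- generate_fish(scz)
  agg <- dplyr::summarise(dplyr::group_by(fz, .data$habitat, .data$month),
                          sl = mean(.data$standard_length_mm),
                          mass = mean(.data$wet_mass_g), .groups = "drop")
  key <- paste(agg$habitat, agg$month)
  t1key <- paste(t1$habitat, t1$month)
  expect_equal(agg$sl, t1$mean_sl_mm[match(key, t1key)])
  juv <- !is.na(agg$mass)
  expect_equal(agg$mass[juv], t1$mean_mass_g[match(key, t1key)][juv],
               tolerance = 1e-10)
  # default noise: stratum mean standard lengths lie within 2 SEM over reps
  reps <- lapply(1:10, function(i) {
    f <- generate_fish(synthetic_scenario(seed = 300 + i))
    dplyr::summarise(dplyr::group_by(f, .data$habitat, .data$month),
                     sl = mean(.data$standard_length_mm), .groups = "drop")
  })
  mean_sl <- Reduce(`+`, lapply(reps, function(r) r$sl)) / 10
  key <- paste(reps[[1]]$habitat, reps[[1]]$month)
  idx <- match(key, t1key)
  # 12 strata tested simultaneously, so use a 3-SE (Bonferroni-scale) band
  expect_true(all(abs(mean_sl - t1$mean_sl_mm[idx]) <
                    3 * t1$sem_sl_mm[idx] / sqrt(10)))
})

test_that("simulated surveys round-trip through the CSV layer", {
  dir <- withr::local_tempdir()
  sc <- synthetic_scenario(seed = 12, consumers_per_stratum = 10L, n_ref = 4L)
  paths <- simulate_survey_csv(sc, dir)
  expect_true(all(file.exists(paths)))
  svy <- generate_survey(sc)
  back <- read_survey_csv(paths[["consumers"]], "consumer_isotopes")
  expect_equal(back$d13C_bulk, svy$consumers$d13C_bulk)
  truth <- readr::read_csv(paths[["truth"]], show_col_types = FALSE)
  expect_equal(truth$true_planktonic, svy$truth$true_planktonic)
})
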