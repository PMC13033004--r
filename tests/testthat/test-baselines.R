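test_that("baseline summaries report means, SEs and degenerate cases", {
  s <- make_reference(c("mussel", "mussel"), "pelagic", d13C = c(-27, -27))
  out <- summarize_baselines(s, lipid_correct = FALSE)
  expect_equal(out$mean_d13C, -27)
  expect_equal(out$se_d13C, 0)
  expect_equal(out$n, 2L)
  # single sample: SE absent
  one <- summarize_baselines(make_reference("snail", "littoral", -18),
                             lipid_correct = FALSE)
  expect_equal(one$mean_d13C, -18)
  expect_true(is.na(one$se_d13C))
  # empty input: empty output with warning
  expect_warning(empty <- summarize_baselines(make_reference("snail", "littoral", -18)[0, ]),
                 "no reference")
  expect_equal(nrow(empty), 0)
  # non-reference taxa rejected
  bad <- make_reference("mussel", "pelagic", -27)
  bad$taxon <- "fish_larva"
  expect_error(summarize_baselines(bad), "non-reference")
})

test_that("summaries recover the generating means from noisy draws", {
  set.seed(21)
  n <- 200
  s <- make_reference("zooplankton", "pelagic",
                      d13C = rnorm(n, -27, 1), d15N = rnorm(n, 5.7, 1))
  out <- summarize_baselines(s, lipid_correct = FALSE)
  expect_lt(abs(out$mean_d13C - (-27)), 3 * 1 / sqrt(n))
  expect_lt(abs(out$mean_d15N - 5.7), 3 * 1 / sqrt(n))
})

test_that("invertebrate lipid correction is applied to d13C summaries by default", {
  s <- make_reference("mussel", "pelagic", d13C = c(-25, -25), CN = 8.4)
  out <- summarize_baselines(s)
  expect_equal(out$mean_d13C, -25 + 6.3 * (8.4 - 4.2) / 8.4)
  # d15N untouched
  expect_equal(out$mean_d15N, 5)
})

test_that("with habitat-balanced data pooled means equal the mean of habitat means", {
  set.seed(22)
  s <- draw_reference(10, c(mussel = -28, snail = -18, zooplankton = -27),
                      c(mussel = 5.5, snail = 2.5, zooplankton = 5.7))
  sm <- summarize_baselines(s, lipid_correct = FALSE)
  pooled_m <- tapply(s$d13C_bulk, s$taxon, mean)
  by_hab <- tapply(sm$mean_d13C, sm$taxon, mean)
  expect_equal(as.numeric(by_hab[names(pooled_m)]), as.numeric(pooled_m))
})

test_that("taxon comparisons detect the planktonic/benthic separation", {
  set.seed(23)
  s <- draw_reference(15, c(mussel = -28, snail = -18, zooplankton = -27.5),
                      c(mussel = 5.5, snail = 2.5, zooplankton = 5.6),
                      sd_d13C = 0.8, sd_d15N = 0.6)
  cmp <- compare_baseline_taxa(s, lipid_correct = FALSE)
  expect_equal(nrow(cmp), 6L)
  d13 <- cmp[cmp$element == "d13C", ]
  expect_true(d13$significant[d13$pair == "mussel-snail"])
  expect_true(d13$significant[d13$pair == "snail-zooplankton"])
  expect_false(d13$significant[d13$pair == "mussel-zooplankton"])
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # permutation invariance to row order
  cmp_sh <- compare_baseline_taxa(s[sample(nrow(s)), ], lipid_correct = FALSE)
  expect_equal(cmp_sh[order(cmp_sh$pair, cmp_sh$element), ],
               cmp[order(cmp$pair, cmp$element), ])
})

test_that("taxon comparisons reject degenerate or insufficient input", {
  expect_error(compare_baseline_taxa(make_reference("mussel", "pelagic",
                                                    c(-27, -27.5))),
               "two reference taxa")
  few <- dplyr::bind_rows(make_reference("mussel", "pelagic", c(-27, -27.5)),
                          make_reference("snail", "littoral", -18))
  expect_error(compare_baseline_taxa(few), "at least 2 samples")
  # identical constants within taxa, distinct across: degenerate
  # p -> 0 with a warning (d15N constant and equal across taxa -> p = 1)
  const <- dplyr::bind_rows(
    make_reference(rep("mussel", 3), "pelagic", -28),
    make_reference(rep("snail", 3), "littoral", -18),
    make_reference(rep("zooplankton", 3), "pelagic", -27))
  deg <- suppressWarnings(compare_baseline_taxa(const, lipid_correct = FALSE))
  # both elements are degenerate, so the call warns once per element
  expect_warning(
    expect_warning(compare_baseline_taxa(const, lipid_correct = FALSE),
                   "zero within-taxon variance"),
    "zero within-taxon variance")
  expect_equal(deg$p_value[deg$element == "d13C"], rep(0, 3))
  expect_true(all(deg$significant[deg$element == "d13C"]))
  expect_equal(deg$p_value[deg$element == "d15N"], rep(1, 3))
})

test_that("taxon comparisons hold the Tukey family error rate under the null", {
  set.seed(24)
  n_reps <- 200
  any_sig <- replicate(n_reps, {
    s <- draw_reference(8, c(mussel = -25, snail = -25, zooplankton = -25),
                        c(mussel = 5, snail = 5, zooplankton = 5))
    cmp <- compare_baseline_taxa(s, lipid_correct = FALSE)
    any(cmp$significant[cmp$element == "d13C"])
  })
  rate <- mean(any_sig)
  # familywise rate should sit near alpha = 0.05
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("proxy adequacy ratio implements the ten-fold criterion", {
  sm <- tibble::tibble(
    taxon = c("mussel", "snail", "zooplankton"),
    habitat = "pelagic", n = 5L,
    mean_d13C = c(-28, -18, -27), se_d13C = 0.1,
    mean_d15N = c(5.5, 2.5, 5.7), se_d15N = 0.1
  )
  pa <- proxy_adequacy(sm)
  expect_equal(pa$ratio, 10)
  expect_true(pa$pass)
  # mussel == zooplankton: infinite ratio reported as PASS with flag
  sm2 <- sm; sm2$mean_d13C <- c(-28, -18, -28)
  pa2 <- proxy_adequacy(sm2)
  expect_true(is.infinite(pa2$ratio))
  expect_true(pa2$pass && pa2$infinite_denominator)
  # weak separation fails
  sm3 <- sm; sm3$mean_d13C <- c(-28, -27, -26)
  pa3 <- proxy_adequacy(sm3)
  expect_equal(pa3$ratio, 0.5)
  expect_false(pa3$pass)
})

test_that("the baseline pair is extracted from pelagic mussels and littoral snails", {
  set.seed(25)
  s <- draw_reference(10, c(mussel = -28, snail = -18, zooplankton = -27),
                      c(mussel = 5.5, snail = 2.5, zooplankton = 5.7))
  sm <- summarize_baselines(s, lipid_correct = FALSE)
  bp <- baseline_pair_from_summaries(sm)
  expect_s3_class(bp, "baseline_pair")
  expect_equal(bp$d13C_base1,
               sm$mean_d13C[sm$taxon == "mussel" & sm$habitat == "pelagic"])
  expect_equal(bp$d13C_base2,
               sm$mean_d13C[sm$taxon == "snail" & sm$habitat == "littoral"])
  expect_error(baseline_pair_from_summaries(sm[sm$taxon == "snail", ]),
               "exactly one")
})
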