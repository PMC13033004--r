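test_that("response transforms match their closed forms and clamp proportions", {
  x <- c(0, 0.5, 3)
  expect_equal(transform_response(x, "log1p"), log(x + 1))
  expect_equal(transform_response(c(0, 0.25, 1), "arcsine_sqrt"),
               asin(sqrt(c(0, 0.25, 1))))
  expect_warning(y <- transform_response(c(-0.1, 0.5, 1.2), "arcsine_sqrt"),
                 "clamped")
  expect_equal(y, asin(sqrt(c(0, 0.5, 1))))
  expect_error(transform_response(c(-1, 2), "log1p"), "nonnegative")
})

test_that("two-factor ANOVA on transformed data equals plain ANOVA on pre-transformed data", {
  set.seed(31)
  d <- tibble::tibble(
    habitat = rep(c("littoral", "shoreline", "pelagic"), each = 20),
    month = rep(rep(c("June", "July"), each = 10), times = 3),
    density = rexp(60, 0.5)
  )
  a1 <- two_factor_anova(d, "density", "log1p")
  d2 <- d
  d2$density <- log(d$density + 1)
  a2 <- two_factor_anova(d2, "density", "none")
  expect_equal(a1$F, a2$F)
  expect_equal(a1$p, a2$p)
})

test_that("two-factor ANOVA handles degenerate and invalid designs", {
  d <- tibble::tibble(habitat = rep(c("a", "b"), each = 4),
                      month = rep(c("June", "July"), times = 4),
                      y = 1)
  out <- two_factor_anova(d, "y")
  expect_equal(out$F, rep(0, 3))
  expect_equal(out$p, rep(1, 3))
  expect_error(two_factor_anova(d[d$habitat == "a", ], "y"), "2 levels")
  # an empty cell warns about the unbalanced design, then the singular
  # interaction fit errors
  d2 <- tibble::tibble(habitat = rep(c("a", "b"), each = 4),
                       month = c(rep("June", 4), rep(c("June", "July"), 2)),
                       y = rnorm(8))
  expect_warning(expect_error(two_factor_anova(d2, "y"), "singular"),
                 "empty habitat x month")
})

test_that("two-factor ANOVA is invariant to row order and label permutation", {
  set.seed(32)
  d <- tibble::tibble(
    habitat = rep(c("littoral", "shoreline", "pelagic"), each = 12),
    month = rep(rep(c("June", "July"), each = 6), times = 3),
    y = rnorm(36)
  )
  a <- two_factor_anova(d, "y")
  a_sh <- two_factor_anova(d[sample(nrow(d)), ], "y")
  expect_equal(a, a_sh)
  d_rel <- d
  d_rel$habitat <- c(littoral = "pelagic", shoreline = "littoral",
                     pelagic = "shoreline")[d$habitat]
  expect_equal(two_factor_anova(d_rel, "y")$F, a$F)
})

test_that("Kruskal-Wallis per month matches the rank-statistic closed form", {
  # tie-free small sample: H = 12/(N(N+1)) * sum n_i (rbar_i - (N+1)/2)^2
  d <- tibble::tibble(
    habitat = rep(c("a", "b", "c"), each = 3),
    month = "June",
    y = c(1.1, 2.3, 9.8, 4.2, 5.1, 6.7, 3.3, 8.5, 7.4)
  )
  r <- rank(d$y)
  rbar <- tapply(r, d$habitat, mean)
  H <- 12 / (9 * 10) * sum(3 * (rbar - 5)^2)
  out <- kruskal_wallis_by_month(d, "y")
  expect_equal(out$statistic, H)
  expect_equal(out$df, 2)
  # extreme separation drives p toward zero
  d2 <- d
  d2$y[d2$habitat == "c"] <- d2$y[d2$habitat == "c"] + 1000
  d2 <- dplyr::bind_rows(d2, d2, d2)  # n = 9 per group
  expect_lt(kruskal_wallis_by_month(d2, "y")$p, 0.01)
  # single habitat in a month: absent result
  expect_equal(nrow(kruskal_wallis_by_month(d[d$habitat == "a", ], "y")), 0)
})

test_that("compact letter displays cover the canonical cases", {
  set.seed(33)
  # three identical groups share one letter
  same <- pairwise_wilcoxon_letters(rep(rnorm(8), 3), rep(c("a", "b", "c"), each = 8))
  expect_equal(unique(same$groups$letters), "a")
  # three fully separated groups get three letters
  sep <- pairwise_wilcoxon_letters(c(rnorm(10), rnorm(10) + 50, rnorm(10) + 100),
                                   rep(c("lo", "mid", "hi"), each = 10))
  expect_setequal(sep$groups$letters, c("a", "b", "c"))
  # chain case A ~ B, B ~ C, A != C -> letters a / ab / b
  A <- c(1, 2, 3, 4, 5, 6, 7, 8)
  B <- A + 2.25
  C <- A + 4.5
  chain <- pairwise_wilcoxon_letters(c(A, B, C),
                                     rep(c("A", "B", "C"), each = 8))
  pm <- chain$p_matrix
  expect_gte(pm["A", "B"], 0.05)
  expect_gte(pm["B", "C"], 0.05)
  expect_lt(pm["A", "C"], 0.05)
  lets <- setNames(chain$groups$letters, chain$groups$group)
  expect_equal(nchar(lets[["B"]]), 2L)
  expect_equal(nchar(lets[["A"]]), 1L)
  expect_equal(nchar(lets[["C"]]), 1L)
  expect_false(lets[["A"]] == lets[["C"]])
  expect_true(grepl(lets[["A"]], lets[["B"]]) && grepl(lets[["C"]], lets[["B"]]))
})

test_that("letter displays are consistent with their own p-matrix", {
  set.seed(34)
  for (rep_i in 1:25) {
    g <- rep(c("a", "b", "c"), each = 9)
    y <- rnorm(27) + rep(runif(3, 0, 2), each = 9)
    wl <- pairwise_wilcoxon_letters(y, g, alpha = 0.05)
    lets <- setNames(strsplit(wl$groups$letters, ""), wl$groups$group)
    for (i in c("a", "b")) for (j in setdiff(c("b", "c"), i)) {
      share <- length(intersect(lets[[i]], lets[[j]])) > 0
      if (wl$p_matrix[i, j] < 0.05) expect_false(share)
      else expect_true(share)
    }
  }
})

test_that("condition ANCOVA recovers slopes, adjusted means and residual condition", {
  set.seed(35)
  n <- 40
  sl <- rnorm(3 * n, 25, 2)
  hab <- rep(c("littoral", "shoreline", "pelagic"), each = n)
  slope <- c(littoral = 0.03, shoreline = 0.03, pelagic = 0.03)
  mass <- -0.4 + slope[hab] * sl + rnorm(3 * n, 0, 0.01)
  fish <- make_fish(hab, sl, mass)
  cm <- condition_analysis(fish)
  expect_equal(sort(cm$slopes$habitat), sort(names(slope)))
  expect_equal(cm$slopes$slope, rep(0.03, 3), tolerance = 0.15)
  # equal generating lines: adjusted means agree across habitats
  expect_lt(diff(range(cm$adjusted_means$adjusted_mass_g)), 0.01)
  # a fish exactly on the pooled regression line has residual condition zero
  pooled <- lm(wet_mass_g ~ standard_length_mm, data = fish)
  fish2 <- dplyr::bind_rows(
    fish,
    make_fish("littoral", 25, unname(predict(pooled,
      newdata = data.frame(standard_length_mm = 25)))))
  cm2 <- condition_analysis(fish2)
  resid_new <- cm2$residual_condition$residual[nrow(fish2)]
  # the added point barely moves the pooled fit, so its residual is ~0
  expect_lt(abs(resid_new), 1e-3)
  # residuals of the pooled regression sum to zero
  expect_equal(sum(cm$residual_condition$residual), 0, tolerance = 1e-10)
  expect_error(condition_analysis(fish[1:5, ]), "at least 3")
})

test_that("condition ANCOVA detects a steeper pelagic allometry", {
  set.seed(36)
  detected <- replicate(50, {
    n <- 32
    hab <- rep(c("littoral", "shoreline", "pelagic"), each = n)
    sl <- rnorm(3 * n, 20, 2.5)
    b <- ifelse(hab == "pelagic", 3.3, 3.0)
    a <- ifelse(hab == "pelagic", 0.218 / 22.23^3.3, 0.111 / 18.87^3)
    mass <- a * sl^b * exp(rnorm(3 * n, 0, 0.08))
    cm <- condition_analysis(make_fish(hab, sl, mass, month = "August"))
    cm$interaction$p < 0.05
  })
  expect_gte(mean(detected), 0.9)
})

test_that("Bartlett and Levene variance tests behave on canonical inputs", {
  set.seed(37)
  x <- rnorm(50)
  # duplicated identical groups: statistic ~ 0, p ~ 1
  out <- variance_homogeneity(c(x, x), rep(c("a", "b"), each = 50))
  expect_lt(out$statistic, 1e-10)
  expect_equal(out$p, 1, tolerance = 1e-6)
  # a 4x variance difference is detected at n = 50
  sig <- replicate(30, {
    y <- c(rnorm(50, 0, 1), rnorm(50, 0, 2), rnorm(50, 0, 1))
    variance_homogeneity(y, rep(c("a", "b", "c"), each = 50))$p < 0.05
  })
  expect_gte(mean(sig), 0.9)
  # Levene F-form available
  lev <- variance_homogeneity(c(x, x + 1), rep(c("a", "b"), each = 50),
                              method = "levene")
  expect_equal(lev$test, "levene")
  expect_true(is.finite(lev$statistic))
  # zero-variance group is degenerate
  expect_error(variance_homogeneity(c(rep(1, 5), rnorm(5)),
                                    rep(c("a", "b"), each = 5)),
               "zero variance")
})
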