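#' Response transforms used by the statistical battery
#'
#' `"log1p"` is ln(x + 1), used for zooplankton densities; `"arcsine_sqrt"`
#' is arcsin(sqrt(p)) on proportions, used for %-planktonic values divided
#' by 100 (inputs outside \[0, 1\] are clamped with a warning, as mixing
#' estimates can fall slightly outside the end-members); `"none"` is the
#' identity.
#'
#' @param x numeric response values.
#' @param transform one of `"none"`, `"log1p"`, `"arcsine_sqrt"`.
#' @return Transformed values.
#' @export
transform_response <- function(x, transform = c("none", "log1p", "arcsine_sqrt")) {
  transform <- match.arg(transform)
  switch(transform,
    none = x,
    log1p = {
      if (any(x < 0, na.rm = TRUE)) {
        stop("log1p transform requires nonnegative values", call. = FALSE)
      }
      log(x + 1)
    },
    arcsine_sqrt = {
      oob <- !is.na(x) & (x < 0 | x > 1)
      if (any(oob)) {
        warning(sum(oob), " proportion(s) outside [0, 1] clamped before ",
                "arcsine transform", call. = FALSE)
        x <- pmin(pmax(x, 0), 1)
      }
      asin(sqrt(x))
    }
  )
}

#' Two-factor ANOVA with interaction (habitat x month)
#'
#' The screening model of the battery: a two-factor linear model with
#' interaction partitioning response variation among habitats, months and
#' their interaction, fitted after the chosen transform. Sum-to-zero
#' contrasts with partial (type III) sums of squares are used so the tests
#' are well defined for unbalanced designs; empty habitat x month cells
#' raise a warning.
#'
#' @param data a tibble with the response and `habitat`, `month` columns.
#' @param response name of the response column (string).
#' @param transform see [transform_response()].
#' @return A tibble with rows Habitat, Month, Habitat:Month and Residuals:
#'   `term`, `df`, `F`, `p`. A response with zero total variance returns
#'   F = 0, p = 1 for every term.
#' @export
two_factor_anova <- function(data, response,
                             transform = c("none", "log1p", "arcsine_sqrt")) {
  transform <- match.arg(transform)
  dat <- tibble::tibble(
    y = transform_response(data[[response]], transform),
    habitat = factor(data$habitat),
    month = factor(data$month)
  )
  dat <- dat[stats::complete.cases(dat), ]
  if (nlevels(droplevels(dat$habitat)) < 2 ||
      nlevels(droplevels(dat$month)) < 2) {
    stop("two_factor_anova needs at least 2 levels of habitat and month",
         call. = FALSE)
  }
  dat$habitat <- droplevels(dat$habitat)
  dat$month <- droplevels(dat$month)
  cells <- table(dat$habitat, dat$month)
  if (any(cells == 0)) {
    warning("empty habitat x month cell(s); design is unbalanced and the ",
            "interaction may be inestimable", call. = FALSE)
  }
  terms_out <- c("Habitat", "Month", "Habitat:Month")
  if (stats::var(dat$y) < .Machine$double.eps * 100) {
    return(tibble::tibble(term = terms_out,
                          df = NA_integer_, F = 0, p = 1))
  }
  fit <- stats::lm(y ~ habitat * month, data = dat,
                   contrasts = list(habitat = "contr.sum",
                                    month = "contr.sum"))
  if (any(is.na(stats::coef(fit)))) {
    stop("singular two-factor fit (inestimable cells)", call. = FALSE)
  }
  aov_tab <- car::Anova(fit, type = 3)
  rows <- c("habitat", "month", "habitat:month")
  idx <- match(rows, rownames(aov_tab))
  tibble::tibble(
    term = terms_out,
    df = aov_tab$Df[idx],
    df_den = stats::df.residual(fit),
    F = aov_tab$`F value`[idx],
    p = aov_tab$`Pr(>F)`[idx]
  )
}

#' Kruskal-Wallis habitat test, separately per month
#'
#' Rank-based comparison of habitats run separately in each month (the
#' follow-up used when heteroscedasticity across habitats makes the
#' parametric model untrustworthy). Ties are handled by midranks.
#'
#' @inheritParams two_factor_anova
#' @return A tibble with one row per month having at least two habitats:
#'   `month`, `test`, `statistic` (chi-square), `df`, `p`, `n`.
#' @export
kruskal_wallis_by_month <- function(data, response) {
  dat <- tibble::tibble(
    y = data[[response]], habitat = as.character(data$habitat),
    month = data$month
  )
  dat <- dat[stats::complete.cases(dat), ]
  months_present <- levels(factor(dat$month))
  out <- lapply(months_present, function(m) {
    d <- dat[dat$month == m, ]
    if (length(unique(d$habitat)) < 2) return(NULL)
    if (stats::var(d$y) < .Machine$double.eps * 100) {
      # all values tied: no evidence of habitat differences
      return(tibble::tibble(month = m, test = "kruskal_wallis",
                            statistic = 0,
                            df = length(unique(d$habitat)) - 1, p = 1,
                            n = nrow(d)))
    }
    kw <- stats::kruskal.test(d$y, factor(d$habitat))
    tibble::tibble(month = m, test = "kruskal_wallis",
                   statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p = kw$p.value,
                   n = nrow(d))
  })
  dplyr::bind_rows(out)
}

# pairwise Wilcoxon rank-sum p-value matrix; exact distribution when both
# groups are small and tie-free, otherwise normal approximation with
# continuity correction
pairwise_wilcoxon_p <- function(values, groups, exact_max_n = 10,
                                adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  g <- sort(unique(groups))
  if (length(g) < 2) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(g, 2, simplify = FALSE)
  pvals <- vapply(pairs, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    use_exact <- length(x) <= exact_max_n && length(y) <= exact_max_n &&
      !anyDuplicated(c(x, y))
    suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
  }, double(1))
  # fully tied comparisons have zero rank variance; treat as no evidence
  pvals[!is.finite(pvals)] <- 1
  pvals <- stats::p.adjust(pvals, method = adjust)
  pm <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(pairs)) {
    pm[pairs[[i]][1], pairs[[i]][2]] <- pvals[i]
    pm[pairs[[i]][2], pairs[[i]][1]] <- pvals[i]
  }
  diag(pm) <- 1
  pm
}

# compact letter display via the maximal cliques of the non-significance
# graph (groups are vertices, edges join pairs with p >= alpha). Every
# non-significant pair then shares a letter and no significant pair does.
# Group counts here are small (habitats), so cliques are enumerated by
# exhaustive subset search; letters are ordered by the best ordering
# statistic (typically the group median) among a clique's members, ties
# broken lexicographically, so the display is deterministic.
assign_letters <- function(p_matrix, order_stat, alpha = 0.05) {
  g <- rownames(p_matrix)
  k <- length(g)
  if (k > 20) stop("letter display supports at most 20 groups", call. = FALSE)
  adj <- p_matrix >= alpha
  diag(adj) <- TRUE
  subsets <- lapply(seq_len(2^k - 1), function(m) {
    which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
  })
  is_clique <- vapply(subsets, function(s) all(adj[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(cl)
      length(cl) > length(cliques[[i]]) && all(cliques[[i]] %in% cl),
      logical(1)))
  }, logical(1))
  cliques <- cliques[maximal]
  best <- vapply(cliques, function(cl) max(order_stat[cl]), double(1))
  names_key <- vapply(cliques, function(cl) paste(sort(g[cl]), collapse = ","),
                      character(1))
  cliques <- cliques[order(-best, names_key)]
  letters_vec <- letters[seq_along(cliques)]
  vapply(seq_len(k), function(i) {
    paste(sort(letters_vec[vapply(cliques, function(cl) i %in% cl,
                                  logical(1))]), collapse = "")
  }, character(1)) |> stats::setNames(g)
}

#' Pairwise Wilcoxon comparisons with a compact letter display
#'
#' All pairwise rank-sum tests among habitats plus a compact letter
#' display: habitats sharing a letter are not significantly different at
#' `alpha`. Letters are assigned from the maximal cliques of the
#' non-significance graph, ordered by group median (deterministic), so
#' every non-significant pair shares a letter and no significant pair
#' does. Exact p-values are used when both groups have
#' at most `exact_max_n` tie-free observations, otherwise the normal
#' approximation with continuity correction.
#'
#' @param values numeric response values.
#' @param groups group labels (e.g. habitat).
#' @param alpha significance level for the letter display (default 0.05).
#' @param adjust multiplicity adjustment across the pairwise tests:
#'   `"none"` (default, matching an unadjusted alpha = 0.05 battery) or
#'   `"holm"`.
#' @param exact_max_n largest per-group n for the exact null distribution.
#' @return A list of class `"wilcoxon_letters"`: `groups` tibble (group,
#'   n, median, letters), `pairs` tibble (pair, p), `p_matrix`, `alpha`.
#' @export
pairwise_wilcoxon_letters <- function(values, groups, alpha = 0.05,
                                      adjust = c("none", "holm"),
                                      exact_max_n = 10) {
  adjust <- match.arg(adjust)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  pm <- pairwise_wilcoxon_p(values, groups, exact_max_n, adjust)
  med <- tapply(values, groups, stats::median)[rownames(pm)]
  lets <- assign_letters(pm, order_stat = med, alpha = alpha)
  pairs_idx <- utils::combn(rownames(pm), 2)
  pairs_df <- tibble::tibble(
    pair = paste(pairs_idx[1, ], pairs_idx[2, ], sep = "-"),
    p = pm[cbind(pairs_idx[1, ], pairs_idx[2, ])]
  )
  structure(
    list(
      groups = tibble::tibble(
        group = rownames(pm),
        n = as.integer(table(groups)[rownames(pm)]),
        median = as.numeric(med),
        letters = unname(lets[rownames(pm)])
      ),
      pairs = pairs_df, p_matrix = pm, alpha = alpha
    ),
    class = "wilcoxon_letters"
  )
}

#' @export
print.wilcoxon_letters <- function(x, ...) {
  cat(sprintf("Pairwise Wilcoxon comparisons (alpha = %g):\n", x$alpha))
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' Monthly habitat comparisons: Kruskal-Wallis gate plus letters
#'
#' For each month, runs the Kruskal-Wallis habitat test and, when it is
#' available, the pairwise Wilcoxon letter display. The letter display can
#' be gated on a significant Kruskal-Wallis test.
#'
#' @inheritParams two_factor_anova
#' @inheritParams pairwise_wilcoxon_letters
#' @param gate if `TRUE`, letters are only computed for months whose
#'   Kruskal-Wallis p-value is below `alpha` (all habitats then share "a").
#' @return A list with `kruskal` (tibble from [kruskal_wallis_by_month()])
#'   and `letters` (tibble month x habitat with median and letters).
#' @export
monthly_habitat_comparisons <- function(data, response, alpha = 0.05,
                                        adjust = c("none", "holm"),
                                        gate = FALSE) {
  adjust <- match.arg(adjust)
  kw <- kruskal_wallis_by_month(data, response)
  out <- lapply(kw$month, function(m) {
    d <- data[!is.na(data$month) & data$month == m, ]
    if (gate && kw$p[kw$month == m] >= alpha) {
      habs <- sort(unique(as.character(d$habitat)))
      return(tibble::tibble(month = m, habitat = habs,
                            median = vapply(habs, function(h)
                              stats::median(d[[response]][d$habitat == h],
                                            na.rm = TRUE), double(1)),
                            letters = "a"))
    }
    wl <- pairwise_wilcoxon_letters(d[[response]], d$habitat,
                                    alpha = alpha, adjust = adjust)
    tibble::tibble(month = m, habitat = wl$groups$group,
                   median = wl$groups$median, letters = wl$groups$letters)
  })
  list(kruskal = kw, letters = dplyr::bind_rows(out))
}

#' ANCOVA of body mass on standard length across habitats
#'
#' The body-condition analysis: wet mass regressed on standard length with
#' habitat as a factor. Reports (i) the length x habitat interaction test
#' (heterogeneity of mass-length slopes), (ii) per-habitat slopes, (iii)
#' habitat-adjusted mean masses +/- SE at the grand-mean length with
#' Tukey-adjusted pairwise contrasts, and (iv) each fish's residual-mass
#' condition index from the pooled (all habitats combined) regression.
#' Adjusted means come from the additive model when
#' `drop_interaction = TRUE` (the default, appropriate when slopes are
#' homogeneous) and otherwise from the full interaction model.
#'
#' @param fish a fish tibble (see [survey_schemas]); only rows with wet
#'   mass present (juveniles) are used, and at least 3 such fish per
#'   habitat are required.
#' @param drop_interaction use the additive model for adjusted means.
#' @param alpha significance level carried in the contrast table.
#' @return A list of class `"condition_model"`: `interaction` (F, df, p),
#'   `slopes`, `adjusted_means`, `contrasts`, `residual_condition` (tibble
#'   fish_id, habitat, residual), `n`, `covariate_mean`.
#' @export
condition_analysis <- function(fish, drop_interaction = TRUE, alpha = 0.05) {
  dat <- fish[!is.na(fish$wet_mass_g) & !is.na(fish$standard_length_mm), ]
  counts <- table(dat$habitat)
  if (length(counts) < 2 || any(counts < 3)) {
    stop("condition_analysis needs at least 3 massed fish in each of at ",
         "least 2 habitats", call. = FALSE)
  }
  dat$habitat <- factor(as.character(dat$habitat))
  full <- stats::lm(wet_mass_g ~ standard_length_mm * habitat, data = dat)
  additive <- stats::lm(wet_mass_g ~ standard_length_mm + habitat, data = dat)
  cmp <- stats::anova(additive, full)
  interaction <- tibble::tibble(
    term = "standard_length_mm:habitat",
    F = cmp$F[2], df_num = cmp$Df[2], df_den = cmp$Res.Df[2], p = cmp$`Pr(>F)`[2]
  )
  trends <- as.data.frame(
    emmeans::emtrends(full, "habitat", var = "standard_length_mm"))
  slopes <- tibble::tibble(
    habitat = as.character(trends$habitat),
    slope = trends$standard_length_mm.trend,
    se = trends$SE
  )
  mean_len <- mean(dat$standard_length_mm)
  adj_fit <- if (drop_interaction) additive else full
  emm <- emmeans::emmeans(adj_fit, "habitat",
                          at = list(standard_length_mm = mean_len))
  emm_df <- as.data.frame(emm)
  adjusted_means <- tibble::tibble(
    habitat = as.character(emm_df$habitat),
    adjusted_mass_g = emm_df$emmean,
    se = emm_df$SE
  )
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  contrasts <- tibble::tibble(
    pair = gsub(" - ", "-", ctr$contrast),
    estimate = ctr$estimate, se = ctr$SE,
    t_statistic = ctr$t.ratio, p_value = ctr$p.value,
    significant = ctr$p.value < alpha
  )
  pooled <- stats::lm(wet_mass_g ~ standard_length_mm, data = dat)
  residual_condition <- tibble::tibble(
    fish_id = if ("fish_id" %in% names(dat)) dat$fish_id else NA_character_,
    habitat = as.character(dat$habitat),
    residual = unname(stats::residuals(pooled))
  )
  structure(
    list(interaction = interaction, slopes = slopes,
         adjusted_means = adjusted_means, contrasts = contrasts,
         residual_condition = residual_condition,
         n = nrow(dat), covariate_mean = mean_len,
         drop_interaction = drop_interaction),
    class = "condition_model"
  )
}

#' @export
print.condition_model <- function(x, ...) {
  cat(sprintf("ANCOVA of wet mass on standard length (n = %d fish)\n", x$n))
  cat(sprintf("  length x habitat interaction: F(%d, %d) = %.2f, p = %.4g\n",
              x$interaction$df_num, x$interaction$df_den,
              x$interaction$F, x$interaction$p))
  cat(sprintf("  adjusted means at SL = %.2f mm (%s model):\n",
              x$covariate_mean,
              if (x$drop_interaction) "additive" else "interaction"))
  print(as.data.frame(x$adjusted_means), row.names = FALSE)
  invisible(x)
}

#' Variance homogeneity across habitats
#'
#' Bartlett's chi-square test of equal variances across groups (default),
#' or the Levene/Brown-Forsythe F-form via car. Any group with zero
#' variance makes Bartlett's statistic degenerate and raises an error.
#'
#' @param values numeric response values.
#' @param groups group labels.
#' @param method `"bartlett"` (chi-square) or `"levene"` (F on absolute
#'   deviations from the median).
#' @return A tibble: `test`, `statistic`, `df`, `df_den` (Levene only), `p`.
#' @export
variance_homogeneity <- function(values, groups,
                                 method = c("bartlett", "levene")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups)[keep])
  counts <- table(groups)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("variance_homogeneity needs at least 2 groups with n >= 2",
         call. = FALSE)
  }
  if (method == "bartlett") {
    vars <- tapply(values, groups, stats::var)
    if (any(vars < .Machine$double.eps * 100)) {
      stop("group with zero variance: Bartlett's statistic is degenerate",
           call. = FALSE)
    }
    bt <- stats::bartlett.test(values, groups)
    tibble::tibble(test = "bartlett", statistic = unname(bt$statistic),
                   df = unname(bt$parameter), df_den = NA_integer_,
                   p = bt$p.value)
  } else {
    lt <- car::leveneTest(values ~ groups)
    tibble::tibble(test = "levene", statistic = lt$`F value`[1],
                   df = lt$Df[1], df_den = lt$Df[2], p = lt$`Pr(>F)`[1])
  }
}
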