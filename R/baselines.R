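#' Summarize isotopic baselines per taxon and habitat
#'
#' Per taxon x habitat means, standard errors and sample sizes of delta-13C
#' and delta-15N for the reference taxa (mussel, snail, zooplankton). By
#' default the invertebrate mass-balance lipid correction is applied to
#' delta-13C before summarizing; delta-15N is never corrected.
#'
#' @param samples a tibble of reference isotope samples with columns
#'   `taxon`, `habitat`, `d13C_bulk`, `d15N`, `CN_bulk` (see
#'   [read_survey_csv()] schema `"reference_isotopes"`).
#' @param lipid_correct apply [lipid_correct_invert()] to delta-13C first.
#' @param constants a [lipid_constants()] bundle.
#' @return A tibble with one row per taxon x habitat: `taxon`, `habitat`,
#'   `n`, `mean_d13C`, `se_d13C`, `mean_d15N`, `se_d15N`. Standard errors
#'   are `NA` when n = 1.
#' @export
summarize_baselines <- function(samples, lipid_correct = TRUE,
                                constants = lipid_constants()) {
  if (nrow(samples) == 0) {
    warning("no reference samples supplied; returning empty summary",
            call. = FALSE)
    return(tibble::tibble(
      taxon = character(), habitat = character(), n = integer(),
      mean_d13C = double(), se_d13C = double(),
      mean_d15N = double(), se_d15N = double()
    ))
  }
  unknown <- setdiff(unique(samples$taxon), REFERENCE_TAXA)
  if (length(unknown)) {
    stop("non-reference taxa in baseline input: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  d13C <- if (lipid_correct) {
    lipid_correct_invert(samples$d13C_bulk, samples$CN_bulk, constants)
  } else {
    samples$d13C_bulk
  }
  samples |>
    dplyr::mutate(.d13C = d13C) |>
    dplyr::group_by(.data$taxon, .data$habitat) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_d13C = mean(.data$.d13C),
      se_d13C = if (dplyr::n() > 1) stats::sd(.data$.d13C) / sqrt(dplyr::n()) else NA_real_,
      mean_d15N = mean(.data$d15N),
      se_d15N = if (dplyr::n() > 1) stats::sd(.data$d15N) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$taxon, REFERENCE_TAXA),
                   match(.data$habitat, HABITATS))
}

#' Tukey-family pairwise comparisons among reference taxa
#'
#' Tests whether the three reference taxa differ in mean delta-13C and
#' delta-15N, pooled across habitats: a one-way linear model per element
#' followed by Tukey-adjusted pairwise comparisons of all three taxon
#' pairs. This is the adequacy check behind using mussels as the planktonic
#' end-member: mussels and zooplankton should not differ, while each should
#' differ from snails.
#'
#' @inheritParams summarize_baselines
#' @param alpha significance level carried in the output (default 0.05).
#' @return A tibble with one row per taxon pair x element: `pair`,
#'   `element`, `estimate` (difference in means, per mil), `t_statistic`,
#'   `p_value` (Tukey-adjusted), `adjusted`, `significant`.
#' @export
compare_baseline_taxa <- function(samples, lipid_correct = TRUE,
                                  constants = lipid_constants(),
                                  alpha = 0.05) {
  taxa <- unique(samples$taxon)
  if (length(taxa) < 2) {
    stop("need at least two reference taxa to compare", call. = FALSE)
  }
  counts <- table(samples$taxon)
  if (any(counts < 2)) {
    stop("need at least 2 samples per taxon; too few for: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  d13C <- if (lipid_correct) {
    lipid_correct_invert(samples$d13C_bulk, samples$CN_bulk, constants)
  } else {
    samples$d13C_bulk
  }
  dat <- tibble::tibble(
    taxon = factor(samples$taxon, levels = intersect(REFERENCE_TAXA, taxa)),
    d13C = d13C, d15N = samples$d15N
  )
  one_element <- function(value, element) {
    within_var <- stats::ave(value, dat$taxon, FUN = stats::var)
    if (all(within_var < .Machine$double.eps * 100)) {
      # degenerate: no within-taxon variance, so any between-taxon
      # difference is infinitely significant and equality is certain
      warning("zero within-taxon variance in ", element,
              "; reporting degenerate p-values (0 when means differ, ",
              "1 when equal)", call. = FALSE)
      means <- tapply(value, dat$taxon, mean)
      prs <- utils::combn(levels(dat$taxon), 2)
      diffs <- means[prs[1, ]] - means[prs[2, ]]
      return(tibble::tibble(
        pair = paste(prs[1, ], prs[2, ], sep = "-"),
        element = element,
        estimate = as.numeric(diffs),
        t_statistic = ifelse(diffs == 0, 0, sign(diffs) * Inf),
        p_value = as.numeric(diffs == 0),
        adjusted = TRUE,
        significant = diffs != 0
      ))
    }
    fit <- stats::lm(value ~ taxon, data = dat)
    emm <- emmeans::emmeans(fit, "taxon")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
    tibble::tibble(
      pair = gsub(" - ", "-", prs$contrast),
      element = element,
      estimate = prs$estimate,
      t_statistic = prs$t.ratio,
      p_value = prs$p.value,
      adjusted = TRUE,
      significant = prs$p.value < alpha
    )
  }
  dplyr::bind_rows(one_element(dat$d13C, "d13C"),
                   one_element(dat$d15N, "d15N"))
}

#' Mussel-proxy adequacy ratio
#'
#' Quantifies how safely mussel tissue can stand in for the planktonic
#' end-member: the ratio of the mussel-snail delta-13C separation (the
#' contrast the mixing model resolves) to the mussel-zooplankton
#' separation (the proxy error). A ratio at or above the threshold
#' (default 10, the "ten-fold" criterion) is a PASS.
#'
#' @param summaries output of [summarize_baselines()]; taxa are pooled
#'   across habitats weighting by sample size.
#' @param threshold minimum acceptable ratio (default 10).
#' @return A list of class `"proxy_adequacy"` with `ratio`, `threshold`,
#'   `pass`, `infinite_denominator`, and the pooled means.
#' @export
proxy_adequacy <- function(summaries, threshold = 10) {
  pooled <- summaries |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      mean_d13C = stats::weighted.mean(.data$mean_d13C, .data$n),
      .groups = "drop"
    )
  need <- c("mussel", "snail", "zooplankton")
  if (!all(need %in% pooled$taxon)) {
    stop("proxy adequacy needs pooled means for mussel, snail and ",
         "zooplankton", call. = FALSE)
  }
  m <- pooled$mean_d13C[pooled$taxon == "mussel"]
  s <- pooled$mean_d13C[pooled$taxon == "snail"]
  z <- pooled$mean_d13C[pooled$taxon == "zooplankton"]
  denom <- abs(m - z)
  ratio <- if (denom == 0) Inf else abs(m - s) / denom
  structure(
    list(ratio = ratio, threshold = threshold,
         pass = ratio >= threshold,
         infinite_denominator = !is.finite(ratio),
         mean_mussel = m, mean_snail = s, mean_zooplankton = z),
    class = "proxy_adequacy"
  )
}

#' @export
print.proxy_adequacy <- function(x, ...) {
  cat(sprintf(
    "Mussel-proxy adequacy: |mussel - snail| / |mussel - zooplankton| = %s\n",
    if (is.finite(x$ratio)) sprintf("%.2f", x$ratio) else "Inf"))
  cat(sprintf("  threshold %.1f -> %s%s\n", x$threshold,
              if (x$pass) "PASS" else "FAIL",
              if (x$infinite_denominator) " (zero denominator)" else ""))
  invisible(x)
}

#' Baseline pair from baseline summaries
#'
#' Extracts the two mixing-model end-members from a baseline summary table:
#' the pelagic-sampled mussel mean (planktonic) and the littoral-sampled
#' snail mean (benthic).
#'
#' @inheritParams proxy_adequacy
#' @return A [baseline_pair()].
#' @export
baseline_pair_from_summaries <- function(summaries) {
  m <- summaries[summaries$taxon == "mussel" & summaries$habitat == "pelagic", ]
  s <- summaries[summaries$taxon == "snail" & summaries$habitat == "littoral", ]
  if (nrow(m) != 1 || nrow(s) != 1) {
    stop("baseline summaries must contain exactly one pelagic mussel and ",
         "one littoral snail row", call. = FALSE)
  }
  baseline_pair(m$mean_d13C, s$mean_d13C,
                n_base1 = m$n, n_base2 = s$n,
                se_base1 = m$se_d13C, se_base2 = s$se_d13C)
}

#' Baseline biplot (delta-13C vs delta-15N)
#'
#' Mean +/- SE biplot of reference taxa in isotope space, one point per
#' taxon x habitat. Requires ggplot2.
#'
#' @inheritParams proxy_adequacy
#' @return A ggplot object.
#' @export
plot_baseline_biplot <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$mean_d13C, y = .data$mean_d15N,
                               colour = .data$taxon, shape = .data$habitat)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_d15N - .data$se_d15N,
                                        ymax = .data$mean_d15N + .data$se_d15N),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean_d13C - .data$se_d13C,
                                         xmax = .data$mean_d13C + .data$se_d13C),
                            height = 0.15, na.rm = TRUE) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = expression(delta^13 * C ~ "(‰)"),
                  y = expression(delta^15 * N ~ "(‰)")) +
    ggplot2::theme_minimal()
}
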