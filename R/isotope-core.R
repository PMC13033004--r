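#' Delta notation from raw isotope ratios
#'
#' Converts heavy:light isotope ratios to per-mil delta notation relative to
#' a standard: delta = (R_sample / R_standard - 1) * 1000. For carbon the
#' standard is VPDB, for nitrogen atmospheric N2.
#'
#' @param ratio_sample,ratio_standard positive heavy:light isotope ratios;
#'   vectors are recycled by the usual rules.
#' @return Delta value(s) in per mil.
#' @examples
#' delta_from_ratios(1.001, 1) # 1 per mil
#' @export
delta_from_ratios <- function(ratio_sample, ratio_standard) {
  if (any(!is.finite(ratio_sample)) || any(!is.finite(ratio_standard)) ||
      any(ratio_sample <= 0) || any(ratio_standard <= 0)) {
    stop("isotope ratios must be positive and finite", call. = FALSE)
  }
  (ratio_sample / ratio_standard - 1) * 1000
}

#' Lipid correction for invertebrate reference tissue
#'
#' Mass-balance lipid normalization of bulk delta-13C for invertebrate
#' reference taxa (mussels, snails, zooplankton):
#' d13C_ex = d13C_bulk + D * (C:N_bulk - C:N_ex) / C:N_bulk.
#' The correction is zero at C:N_bulk = C:N_ex (default 4.2), negative
#' below it, and approaches +D (default 6.3 per mil) as C:N grows.
#'
#' @param d13C_bulk bulk (uncorrected) delta-13C, per mil.
#' @param CN_bulk atomic C:N ratio of the sample, > 0.
#' @param constants a [lipid_constants()] bundle.
#' @return Lipid-corrected delta-13C, per mil.
#' @examples
#' lipid_correct_invert(-25, 8.4) # -21.85
#' @export
lipid_correct_invert <- function(d13C_bulk, CN_bulk,
                                 constants = lipid_constants()) {
  if (any(!is.finite(CN_bulk)) || any(CN_bulk <= 0)) {
    stop("CN_bulk must be positive and finite", call. = FALSE)
  }
  d13C_bulk + constants$invert_D *
    (CN_bulk - constants$invert_CNex) / CN_bulk
}

#' Proportional lipid content from C:N
#'
#' Lipid content (percent) of fish tissue inferred from its atomic C:N
#' ratio: L = L_num / (1 + (L_c1 * C:N - L_c2)^-1). Strictly increasing in
#' C:N on its domain C:N > L_c2 / L_c1 (about 3.1504 at the defaults) and
#' bounded above by L_num (93).
#'
#' @inheritParams lipid_correct_invert
#' @return Lipid content L, in (0, L_num).
#' @examples
#' lipid_content(4.0) # about 16.08
#' @export
lipid_content <- function(CN_bulk, constants = lipid_constants()) {
  thr <- constants$L_c2 / constants$L_c1
  if (any(!is.finite(CN_bulk)) || any(CN_bulk <= thr)) {
    stop(sprintf("CN_bulk must exceed %.4f for the lipid-content relation",
                 thr), call. = FALSE)
  }
  constants$L_num / (1 + 1 / (constants$L_c1 * CN_bulk - constants$L_c2))
}

#' Lipid normalization for fish tissue
#'
#' Kiljunen-type lipid normalization of bulk delta-13C for fish tissue:
#' d13C_ex = d13C_bulk + D * (I + a / (1 + b / L)), with L the
#' C:N-inferred lipid content from [lipid_content()]. The correction is
#' strictly positive and strictly increasing in C:N over its domain.
#'
#' @inheritParams lipid_correct_invert
#' @return Lipid-normalized delta-13C, per mil.
#' @examples
#' lipid_correct_fish(-26, 4.0) # about -24.21
#' @export
lipid_correct_fish <- function(d13C_bulk, CN_bulk,
                               constants = lipid_constants()) {
  d13C_bulk + fish_lipid_correction(CN_bulk, constants)
}

# the additive part of the fish normalization; used forward by
# lipid_correct_fish() and backward by the synthetic generator
fish_lipid_correction <- function(CN_bulk, constants = lipid_constants()) {
  L <- lipid_content(CN_bulk, constants)
  constants$fish_D *
    (constants$fish_I + constants$fish_a / (1 + constants$fish_b / L))
}

#' Baseline pair for the two-end-member mixing model
#'
#' Holds the two mixing-model end-members: the planktonic baseline (mean
#' delta-13C of pelagic-sampled mussel tissue, `d13C_base1`) and the benthic
#' baseline (mean delta-13C of littoral-sampled snail tissue, `d13C_base2`).
#'
#' @param d13C_base1 planktonic end-member mean delta-13C, per mil.
#' @param d13C_base2 benthic end-member mean delta-13C, per mil.
#' @param n_base1,n_base2 sample sizes behind each mean (optional).
#' @param se_base1,se_base2 standard errors of each mean, per mil (optional).
#' @return A list of class `"baseline_pair"`.
#' @examples
#' baseline_pair(-28, -18)
#' @export
baseline_pair <- function(d13C_base1, d13C_base2,
                          n_base1 = NA_integer_, n_base2 = NA_integer_,
                          se_base1 = NA_real_, se_base2 = NA_real_) {
  if (!is.finite(d13C_base1) || !is.finite(d13C_base2)) {
    stop("baseline means must be finite", call. = FALSE)
  }
  if (d13C_base1 == d13C_base2) {
    stop("degenerate baselines: the two end-member means are equal, ",
         "the mixing-model denominator is zero", call. = FALSE)
  }
  structure(
    list(d13C_base1 = d13C_base1, d13C_base2 = d13C_base2,
         n_base1 = n_base1, n_base2 = n_base2,
         se_base1 = se_base1, se_base2 = se_base2),
    class = "baseline_pair"
  )
}

#' @export
print.baseline_pair <- function(x, ...) {
  cat("Two-end-member baseline pair (delta-13C, per mil):\n")
  cat(sprintf("  planktonic (pelagic mussel): %.2f (n = %s, se = %s)\n",
              x$d13C_base1, format(x$n_base1), format(x$se_base1)))
  cat(sprintf("  benthic (littoral snail):    %.2f (n = %s, se = %s)\n",
              x$d13C_base2, format(x$n_base2), format(x$se_base2)))
  invisible(x)
}

#' Two-end-member mixing model: percent planktonic tissue
#'
#' Linear attribution of consumer delta-13C between the planktonic and
#' benthic baselines:
#' \%Planktonic = 100 * (d13C_consumer - d13C_base2) / (d13C_base1 - d13C_base2).
#' The consumer value is expected to be lipid-corrected (see
#' [lipid_correct_fish()]). An optional trophic discrimination offset is
#' subtracted from the consumer value before mixing; it defaults to 0,
#' matching the plain two-end-member form.
#'
#' @param d13C_consumer consumer delta-13C value(s), per mil.
#' @param baselines a [baseline_pair()].
#' @param clamp if `TRUE`, truncate estimates to \[0, 100\] and attach a
#'   logical `out_of_range` attribute flagging the truncated values.
#' @param discrimination per-mil trophic discrimination offset (default 0).
#' @return Percent planktonic values; unbounded when `clamp = FALSE`.
#' @examples
#' b <- baseline_pair(-28, -20)
#' percent_planktonic(-26, b) # 75
#' @export
percent_planktonic <- function(d13C_consumer, baselines,
                               clamp = FALSE, discrimination = 0) {
  stopifnot(inherits(baselines, "baseline_pair"))
  p <- 100 * (d13C_consumer - discrimination - baselines$d13C_base2) /
    (baselines$d13C_base1 - baselines$d13C_base2)
  if (clamp) {
    oob <- !is.na(p) & (p < 0 | p > 100)
    p <- pmin(pmax(p, 0), 100)
    attr(p, "out_of_range") <- oob
  }
  p
}
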