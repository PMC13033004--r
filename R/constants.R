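#' Lipid-correction constants
#'
#' Bundle of the constants used by the two lipid-normalization models and
#' the lipid-content relation. Defaults are the published mass-balance and
#' Kiljunen-type values; any constant can be overridden, e.g. from a YAML
#' config (see [run_pipeline()]).
#'
#' @param invert_D per-mil discrimination between lipid and protein carbon
#'   in the invertebrate mass-balance correction (default 6.3).
#' @param invert_CNex mean atomic C:N of lipid-extracted invertebrate
#'   tissue (default 4.2); samples at this C:N receive zero correction.
#' @param fish_D per-mil isotopic difference between protein and lipid in
#'   the fish normalization (default 7.018).
#' @param fish_I intercept constant of the fish normalization (default 0.048).
#' @param fish_a,fish_b shape constants of the fish normalization
#'   (defaults 3.90 and 287).
#' @param L_num,L_c1,L_c2 constants of the lipid-content relation
#'   L = L_num / (1 + (L_c1 * C:N - L_c2)^-1) (defaults 93, 0.246, 0.775).
#'
#' @return A named list of class `"lipid_constants"`.
#' @examples
#' lipid_constants()
#' lipid_constants(invert_D = 6.0)
#' @export
lipid_constants <- function(invert_D = 6.3, invert_CNex = 4.2,
                            fish_D = 7.018, fish_I = 0.048,
                            fish_a = 3.90, fish_b = 287,
                            L_num = 93, L_c1 = 0.246, L_c2 = 0.775) {
  out <- list(
    invert_D = invert_D, invert_CNex = invert_CNex,
    fish_D = fish_D, fish_I = fish_I, fish_a = fish_a, fish_b = fish_b,
    L_num = L_num, L_c1 = L_c1, L_c2 = L_c2
  )
  bad <- !vapply(out, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad)) {
    stop("lipid constants must be finite numeric scalars: ",
         paste(names(out)[bad], collapse = ", "), call. = FALSE)
  }
  structure(out, class = "lipid_constants")
}

#' @export
print.lipid_constants <- function(x, ...) {
  cat("Lipid-correction constants:\n")
  cat(sprintf("  invertebrate mass balance: D = %g, C:N_ex = %g\n",
              x$invert_D, x$invert_CNex))
  cat(sprintf("  fish normalization: D = %g, I = %g, a = %g, b = %g\n",
              x$fish_D, x$fish_I, x$fish_a, x$fish_b))
  cat(sprintf("  lipid content: L = %g / (1 + (%g * C:N - %g)^-1)\n",
              x$L_num, x$L_c1, x$L_c2))
  invisible(x)
}

# factor levels used throughout
HABITATS <- c("littoral", "shoreline", "pelagic")
MONTHS <- c("June", "July", "August", "September")
REFERENCE_TAXA <- c("mussel", "snail", "zooplankton")
CONSUMER_STAGES <- c("larval", "juvenile")
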