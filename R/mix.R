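#' Define a subpopulation mixture
#'
#' A `subpop_mix` describes the composition of the population being recruited
#' from: an ordered set of subpopulation labels (e.g. `"high"`, `"medium"`,
#' `"low"` rates of improvement) and the proportion of the population in each.
#'
#' Proportions are taken literally: they must sum to 1 (within `1e-9`) and no
#' renormalisation is performed, so a typo such as `c(0.6, 0.3)` is rejected
#' rather than silently rescaled. Use [parse_mix()] to accept percentage
#' inputs.
#'
#' @param labels character vector of unique subpopulation names.
#' @param proportions numeric vector, same length as `labels`; each in
#'   `[0, 1]`, summing to 1 within `1e-9`.
#'
#' @return An object of class `subpop_mix`: a list with elements `labels` and
#'   `proportions` (named by label).
#'
#' @examples
#' subpop_mix(c("high", "low"), c(0.5, 0.5))
#' subpop_mix(c("high", "medium", "low"), c(0.55, 0.35, 0.10))
#' @seealso [study_mixes()] for the four mixtures used in the reference
#'   scenarios, [sample_cohort()] to draw from a mix.
#' @export
subpop_mix <- function(labels, proportions) {
  labels <- as.character(labels)
  proportions <- as.numeric(proportions)
  if (length(labels) < 1L)
    stop("a mix needs at least one subpopulation label", call. = FALSE)
  if (length(labels) != length(proportions))
    stop("'labels' and 'proportions' must have the same length", call. = FALSE)
  if (anyDuplicated(labels))
    stop("subpopulation labels must be unique", call. = FALSE)
  if (anyNA(proportions) || any(proportions < 0) || any(proportions > 1))
    stop("proportions must all lie in [0, 1]", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop(sprintf("proportions must sum to 1 (got %.10g); no renormalisation is performed",
                 sum(proportions)), call. = FALSE)
  structure(list(labels = labels,
                 proportions = stats::setNames(proportions, labels)),
            class = "subpop_mix")
}

#' @export
print.subpop_mix <- function(x, ...) {
  cat("Subpopulation mix (", length(x$labels), " subpopulations)\n", sep = "")
  cat(paste0("  ", format(x$labels), "  ",
             format(100 * x$proportions, nsmall = 1), "%", collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}

#' Parse a label-to-proportion mapping from configuration input
#'
#' Configuration files may give mixture ratios either as fractions (summing
#' to 1) or as percentages (summing to 100). The format is detected by which
#' total the values are closer to, and percentages are divided by 100 before
#' validation by [subpop_mix()].
#'
#' @param x a named numeric vector or named list, label -> proportion or
#'   label -> percentage.
#' @return A validated [subpop_mix()].
#' @examples
#' parse_mix(c(high = 60, low = 40))    # percentages
#' parse_mix(c(high = 0.6, low = 0.4))  # fractions
#' @export
parse_mix <- function(x) {
  vals <- unlist(x)
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    stop("mix entries must be named by subpopulation label", call. = FALSE)
  total <- sum(vals)
  if (abs(total - 100) < abs(total - 1)) vals <- vals / 100
  subpop_mix(names(vals), vals)
}

#' The four reference population mixtures
#'
#' The named mixtures used throughout the reference simulation scenarios:
#' two subpopulations in equal (50/50) or unequal (60/40) ratios, and three
#' subpopulations in equal (1/3 each) or unequal (55/35/10) ratios.
#'
#' @return A named list of [subpop_mix()] objects with names
#'   `"2-equal"`, `"3-equal"`, `"2-unequal"`, `"3-unequal"`.
#' @examples
#' study_mixes()[["2-unequal"]]
#' @export
study_mixes <- function() {
  list(
    "2-equal"   = subpop_mix(c("high", "low"), c(0.5, 0.5)),
    "3-equal"   = subpop_mix(c("high", "medium", "low"), rep(1 / 3, 3)),
    "2-unequal" = subpop_mix(c("high", "low"), c(0.6, 0.4)),
    "3-unequal" = subpop_mix(c("high", "medium", "low"), c(0.55, 0.35, 0.10))
  )
}
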