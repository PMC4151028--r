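#' Exact enumeration of sampling-and-assignment outcomes
#'
#' Under i.i.d. recruitment and a uniformly random split into two equal
#' groups, the two group compositions are independent multinomial
#' `(cell_size, proportions)` vectors; equivalently, the cohort composition
#' is multinomial in `2 * cell_size` subjects and the experimental half is a
#' multivariate hypergeometric draw from it. `enumerate_outcomes()` lists
#' every distinguishable outcome class -- a (cohort composition,
#' experimental-group composition) pair -- with its exact probability, which
#' is sufficient for every registered balance test. The outcome space is
#' small for up to three subpopulations (`choose(n + k - 1, k - 1)^2`
#' classes), so exact rejection probabilities are cheap.
#'
#' @param mix a [subpop_mix()] with at most 3 labels.
#' @param cell_size subjects per group, at most 60 (beyond this guard, use
#'   the Monte Carlo engine [run_scenario()] instead).
#' @return An `outcome_weights` object: list with integer matrices
#'   `composition` (cohort label counts, one row per outcome class) and
#'   `split` (experimental-group label counts), numeric `probability`
#'   (summing to 1), plus `mix` and `cell_size`.
#' @examples
#' ow <- enumerate_outcomes(subpop_mix(c("high", "low"), c(0.5, 0.5)), 2)
#' sum(ow$probability)
#' @export
enumerate_outcomes <- function(mix, cell_size) {
  stopifnot(inherits(mix, "subpop_mix"))
  k <- length(mix$labels)
  if (k > 3)
    stop("exact enumeration is guarded to k <= 3 subpopulations; ",
         "use the Monte Carlo engine for larger k", call. = FALSE)
  if (cell_size > 60)
    stop("exact enumeration is guarded to cell_size <= 60; ",
         "use the Monte Carlo engine for larger cells", call. = FALSE)
  if (cell_size < 1) stop("'cell_size' must be >= 1", call. = FALSE)
  g <- split_grid(k, as.integer(cell_size))
  lp <- comp_log_pmf(g$comps, mix$proportions)     # one group's multinomial
  prob <- exp(lp[g$ie] + lp[g$ic])
  structure(list(composition = g$comps[g$ie, , drop = FALSE] +
                               g$comps[g$ic, , drop = FALSE],
                 split = g$comps[g$ie, , drop = FALSE],
                 probability = prob, mix = mix,
                 cell_size = as.integer(cell_size)),
            class = "outcome_weights")
}

#' @export
print.outcome_weights <- function(x, ...) {
  cat("Exact outcome enumeration: ", length(x$probability),
      " outcome classes, cell size ", x$cell_size,
      sprintf(", total probability %.12f\n", sum(x$probability)), sep = "")
  invisible(x)
}

# compositions of n into k parts and the index pairs (experimental, control);
# geometry depends only on (k, n), so it is cached across mixes and variants
.oracle_cache <- new.env(parent = emptyenv())

split_grid <- function(k, n) {
  key <- paste0("g", k, ".", n)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  comps <- if (k == 1L) matrix(n, 1L, 1L)
           else if (k == 2L) cbind(0:n, n:0)
           else {
             a <- rep(0:n, times = (n + 1L):1L)
             b <- unlist(lapply(0:n, function(x) 0:(n - x)))
             cbind(a, b, n - a - b)
           }
  m <- nrow(comps)
  g <- list(comps = comps,
            ie = rep(seq_len(m), each = m),
            ic = rep(seq_len(m), times = m))
  .oracle_cache[[key]] <- g
  g
}

comp_log_pmf <- function(comps, p) {
  lp <- lgamma(rowSums(comps) + 1) - rowSums(lgamma(comps + 1))
  for (j in seq_len(ncol(comps)))
    lp <- lp + ifelse(comps[, j] == 0L, 0, comps[, j] * log(p[j]))
  lp
}

# per-(variant, k, n) p-values over the outcome classes; independent of the
# mixing proportions, so cached once
variant_pvalues <- function(variant, k, n) {
  key <- paste0("p.", variant, ".", k, ".", n)
  if (!is.null(.oracle_cache[[key]])) return(.oracle_cache[[key]])
  g <- split_grid(k, n)
  e <- g$comps[g$ie, , drop = FALSE]
  f <- g$comps[g$ic, , drop = FALSE]
  pv <- get_variant(variant)$pvec(e, f)
  .oracle_cache[[key]] <- pv
  pv
}

#' Exact unbalanced-sample probability
#'
#' Sums the exact probabilities of all outcome classes whose contingency
#' table is flagged unbalanced (`p < alpha`) by the chosen test variant:
#' the quantity the Monte Carlo engine estimates, computed without
#' simulation error. With `one_sided_favored`, only outcomes in which the
#' experimental group holds a strict excess of that label are counted
#' (the directional remedy).
#'
#' @inheritParams enumerate_outcomes
#' @param variant registered variant name (see [test_variants()]).
#' @param alpha significance threshold.
#' @param one_sided_favored optional label name; restricts to outcomes where
#'   the experimental group has strictly more of this label.
#' @return A probability in `[0, 1]`.
#' @examples
#' mix <- subpop_mix(c("high", "low"), c(0.5, 0.5))
#' exact_unbalanced_rate(mix, 2, variant = "two-sample")   # exactly 0.125
#' @export
exact_unbalanced_rate <- function(mix, cell_size, variant = "two-sample-yates",
                                  alpha = 0.05, one_sided_favored = NULL) {
  ow <- enumerate_outcomes(mix, cell_size)
  pv <- variant_pvalues(variant, length(mix$labels), ow$cell_size)
  flag <- pv < alpha
  if (!is.null(one_sided_favored)) {
    j <- match(one_sided_favored, mix$labels)
    if (is.na(j))
      stop("'one_sided_favored' must be one of: ",
           paste(mix$labels, collapse = ", "), call. = FALSE)
    flag <- flag & (2L * ow$split[, j] > ow$composition[, j])
  }
  sum(ow$probability[flag])
}

#' Calibrate test variants against published reference rates
#'
#' The published unbalanced-sample percentages under-determine the balance
#' test that produced them (the unequal-ratio cells in particular cannot
#' arise from any correctly sized two-sample test, whose rejection rate
#' cannot grow far beyond alpha with the cell size). This computes, for
#' every registered two-sided variant, the *exact* unbalanced rate in each
#' reference cell, scores each variant by the L1 discrepancy
#' `sum(|exact - printed/100|)`, and flags per cell whether the printed
#' value lies within 3 Monte Carlo standard errors (at the study's draw
#' count) of the variant's exact rate.
#'
#' Calibration is reported, never silently applied: the package default
#' stays `"two-sample-yates"`. The `selected` element names the first-ranked
#' variant that is within-3-SE consistent in every cell, falling back to the
#' default when -- as for these reference rates -- no variant explains all
#' cells.
#'
#' @param printed_rates data.frame with columns `mix` (a [study_mixes()]
#'   name), `cell_size` and `percent`; default [reference_rates()]. Must
#'   cover the full mix x cell-size grid.
#' @param variants character vector of registered variant names to score.
#' @param cell_sizes the cell sizes the grid must cover.
#' @param alpha significance threshold.
#' @param draws draw count used for the reference estimates (sets the MC SE
#'   scale of the consistency flags).
#' @return A `variant_calibration`: list with `report` (one row per variant
#'   x cell: exact rate, printed percent, absolute difference, within-3-SE
#'   flag), `ranking` (variants sorted by ascending discrepancy, with the
#'   number of consistent cells) and `selected`.
#' @examples
#' \donttest{
#' cal <- calibrate_variants()
#' cal$ranking
#' }
#' @export
calibrate_variants <- function(printed_rates = reference_rates(),
                               variants = setdiff(test_variants(),
                                                  "two-sample-yates-directional"),
                               cell_sizes = c(20, 40), alpha = 0.05,
                               draws = 10000) {
  mixes <- study_mixes()
  needed <- expand.grid(mix = names(mixes), cell_size = cell_sizes,
                        stringsAsFactors = FALSE)
  have <- paste(printed_rates$mix, printed_rates$cell_size)
  missing <- setdiff(paste(needed$mix, needed$cell_size), have)
  if (length(missing))
    stop("'printed_rates' is missing cells: ", paste(missing, collapse = "; "),
         call. = FALSE)
  rows <- list()
  for (v in variants) {
    for (i in seq_len(nrow(needed))) {
      cell <- needed[i, ]
      printed <- printed_rates$percent[have == paste(cell$mix, cell$cell_size)][1L]
      ex <- exact_unbalanced_rate(mixes[[cell$mix]], cell$cell_size, v, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, mix = cell$mix, cell_size = cell$cell_size,
        exact_rate = ex, printed_percent = printed,
        abs_diff = abs(ex - printed / 100),
        within_3se = abs(ex - printed / 100) <= 3 * mc_standard_error(ex, draws))
    }
  }
  report <- do.call(rbind, rows)
  ranking <- do.call(rbind, lapply(split(report, report$variant), function(d)
    data.frame(variant = d$variant[1L], discrepancy = sum(d$abs_diff),
               n_consistent = sum(d$within_3se), n_cells = nrow(d))))
  ranking <- ranking[order(ranking$discrepancy), ]
  rownames(ranking) <- NULL
  consistent <- ranking$variant[ranking$n_consistent == ranking$n_cells]
  structure(list(report = report, ranking = ranking,
                 selected = if (length(consistent)) consistent[1L]
                            else "two-sample-yates",
                 fully_consistent = length(consistent) > 0L),
            class = "variant_calibration")
}

#' @export
print.variant_calibration <- function(x, ...) {
  cat("Variant calibration against published reference rates\n\n")
  print(x$ranking, row.names = FALSE)
  cat("\nSelected variant: ", x$selected,
      if (!x$fully_consistent)
        " (default; no registered variant is consistent with every reference cell)",
      "\n", sep = "")
  invisible(x)
}
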