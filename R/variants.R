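#' Balance-test variant registry
#'
#' The balance test is applied tens of thousands of times per scenario and,
#' in the exact oracle, to every enumerable table at once; each registered
#' variant therefore provides both a per-table function (returning a full
#' `balance_test_result`) and a vectorised kernel mapping whole matrices of
#' group compositions to p-values. Registered variants:
#'
#' * `"two-sample-yates"` (default) -- Pearson independence test of the 2 x k
#'   table, continuity correction at df = 1 ([pearson_chi_squared()]).
#' * `"two-sample"` -- the same without the continuity correction.
#' * `"gof-uniform-either"`, `"gof-uniform-both"`, `"gof-uniform-pooled"` --
#'   per-group goodness-of-fit against a uniform composition
#'   ([goodness_of_fit_uniform()]), candidate readings of the balance test
#'   for unequal mixing ratios kept for calibration.
#' * `"two-sample-yates-directional"` -- the one-sided remedy: flags only
#'   two-sided-significant tables in which the experimental group holds an
#'   excess of the first (highest-rate) label. Its "p-value" is a decision
#'   score: the two-sided p when the direction is adverse to the hypothesis
#'   being mimicked, and 1 otherwise, so that `p < alpha` reproduces
#'   [one_sided_unbalanced()] exactly.
#'
#' @name variants
NULL

# vectorised kernels --------------------------------------------------------
# e, f: matrices of experimental / control label counts, one row per table,
# equal row sums (the cell size). Return per-row p-values.

pvec_two_sample <- function(e, f, correct) {
  cc <- e + f
  pos <- cc > 0
  keff <- rowSums(pos)
  df <- keff - 1L
  dev <- abs(e - cc / 2)
  if (correct) {
    devy <- pmax(dev - 0.5, 0)
    # correction only where the reduced table is 2 x 2
    dev <- ifelse(matrix(df == 1L, nrow(e), ncol(e)), devy, dev)
  }
  stat <- rowSums(ifelse(pos, 4 * dev^2 / ifelse(pos, cc, 1), 0))
  ifelse(df < 1L, 1, stats::pchisq(stat, pmax(df, 1L), lower.tail = FALSE))
}

pvec_gof_uniform <- function(e, f, combination) {
  k <- ncol(e)
  if (k == 1L) return(rep(1, nrow(e)))
  gof_p <- function(o) {
    expct <- rowSums(o) / k
    stats::pchisq(rowSums((o - expct)^2) / expct, k - 1L, lower.tail = FALSE)
  }
  switch(combination,
         either = pmin(gof_p(e), gof_p(f)),
         both   = pmax(gof_p(e), gof_p(f)),
         pooled = gof_p(e + f))
}

pvec_directional <- function(e, f) {
  ifelse(e[, 1L] > f[, 1L], pvec_two_sample(e, f, correct = TRUE), 1)
}

# registry -------------------------------------------------------------------

variant_registry <- local({
  reg <- list(
    "two-sample-yates" = list(
      family = "two-sample-independence", correction = TRUE,
      table_fun = function(table, alpha) pearson_chi_squared(table, TRUE, alpha),
      pvec = function(e, f) pvec_two_sample(e, f, TRUE)),
    "two-sample" = list(
      family = "two-sample-independence", correction = FALSE,
      table_fun = function(table, alpha) pearson_chi_squared(table, FALSE, alpha),
      pvec = function(e, f) pvec_two_sample(e, f, FALSE)),
    "gof-uniform-either" = list(
      family = "goodness-of-fit-uniform", combination = "either",
      table_fun = function(table, alpha) goodness_of_fit_uniform(table, "either", alpha),
      pvec = function(e, f) pvec_gof_uniform(e, f, "either")),
    "gof-uniform-both" = list(
      family = "goodness-of-fit-uniform", combination = "both",
      table_fun = function(table, alpha) goodness_of_fit_uniform(table, "both", alpha),
      pvec = function(e, f) pvec_gof_uniform(e, f, "both")),
    "gof-uniform-pooled" = list(
      family = "goodness-of-fit-uniform", combination = "pooled",
      table_fun = function(table, alpha) goodness_of_fit_uniform(table, "pooled", alpha),
      pvec = function(e, f) pvec_gof_uniform(e, f, "pooled")),
    "two-sample-yates-directional" = list(
      family = "two-sample-independence", correction = TRUE, directional = TRUE,
      table_fun = function(table, alpha) {
        res <- pearson_chi_squared(table, TRUE, alpha)
        if (table[1L, 1L] <= table[2L, 1L]) {
          res$p_value <- 1
          res$unbalanced <- FALSE
        }
        res$variant <- "two-sample-yates-directional"
        res
      },
      pvec = pvec_directional)
  )
  for (nm in names(reg)) reg[[nm]]$name <- nm
  reg
})

#' @describeIn variants names of all registered variants.
#' @export
test_variants <- function() names(variant_registry)

#' @describeIn variants fetch a registered variant by name (errors with the
#'   list of registered names on an unknown name).
#' @param name variant name.
#' @export
get_variant <- function(name) {
  v <- variant_registry[[name]]
  if (is.null(v))
    stop("unknown test variant '", name, "'; registered variants: ",
         paste(test_variants(), collapse = ", "), call. = FALSE)
  v
}

#' @describeIn variants apply a variant to a single contingency table.
#' @param table 2 x k contingency table.
#' @param alpha significance threshold.
#' @export
apply_variant <- function(name, table, alpha = 0.05) {
  get_variant(name)$table_fun(table, alpha)
}
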