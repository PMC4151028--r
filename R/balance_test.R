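#' Build the group-by-subpopulation contingency table
#'
#' Cross-tabulates group membership (rows: experimental, control) against
#' subpopulation label (columns, in mix label order, zero-count labels
#' included). This 2 x k table is the input to every balance test.
#'
#' @param assignment a `group_assignment`.
#' @param cohort the cohort it was built from.
#' @return Integer matrix with rows `experimental` / `control` and one column
#'   per mix label.
#' @examples
#' set.seed(1)
#' coh <- sample_cohort(study_mixes()[["2-equal"]], 40)
#' build_table(random_split(coh, 20), coh)
#' @export
build_table <- function(assignment, cohort) {
  stopifnot(inherits(assignment, "group_assignment"),
            inherits(cohort, "cohort"))
  k <- length(cohort$mix$labels)
  tab <- rbind(experimental = tabulate(cohort$subpop[assignment$experimental], k),
               control      = tabulate(cohort$subpop[assignment$control], k))
  colnames(tab) <- cohort$mix$labels
  tab
}

new_balance_result <- function(statistic, df, p_value, variant, alpha) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 variant = variant, alpha = alpha,
                 unbalanced = p_value < alpha),
            class = "balance_test_result")
}

#' @export
print.balance_test_result <- function(x, ...) {
  cat(sprintf("Balance test (%s): X-squared = %.4g, df = %d, p = %.4g -> %s at alpha = %g\n",
              x$variant, x$statistic, x$df, x$p_value,
              if (x$unbalanced) "UNBALANCED" else "balanced", x$alpha))
  invisible(x)
}

check_table <- function(table) {
  if (!is.matrix(table) || nrow(table) != 2L || ncol(table) < 1L)
    stop("expected a 2 x k contingency table with at least one column",
         call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers", call. = FALSE)
}

#' Pearson chi-squared test of group-composition independence
#'
#' Tests whether the two groups differ in subpopulation composition: the
#' Pearson statistic with expected counts from the row/column margins,
#' `df = (columns - 1)` after removing all-zero columns (their expected
#' counts are undefined). The Yates continuity correction -- subtracting up
#' to 0.5 from each `|observed - expected|` -- is applied only when
#' `correction = TRUE` and the reduced table has df = 1; it makes the test
#' conservative at small cell sizes. A table that reduces to a single column
#' carries no composition information and is declared balanced
#' (statistic 0, p = 1).
#'
#' @param table 2 x k integer matrix from [build_table()].
#' @param correction apply the continuity correction at df = 1
#'   (default `TRUE`).
#' @param alpha significance threshold recorded in the result.
#' @return A `balance_test_result`: statistic, df, p_value, variant name and
#'   the unbalanced flag (`p_value < alpha`, strict).
#' @examples
#' pearson_chi_squared(rbind(c(15, 5), c(5, 15)))                    # X2 = 8.1
#' pearson_chi_squared(rbind(c(15, 5), c(5, 15)), correction = FALSE) # X2 = 10
#' @export
pearson_chi_squared <- function(table, correction = TRUE, alpha = 0.05) {
  check_table(table)
  keep <- colSums(table) > 0
  x <- table[, keep, drop = FALSE]
  if (ncol(x) <= 1L)
    return(new_balance_result(0, 0L, 1,
                              if (correction) "two-sample-yates" else "two-sample",
                              alpha))
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  E <- outer(rs, cs) / n
  dev <- abs(x - E)
  df <- ncol(x) - 1L
  if (correction && df == 1L) dev <- dev - min(0.5, dev)
  stat <- sum(dev^2 / E)
  new_balance_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                     if (correction) "two-sample-yates" else "two-sample",
                     alpha)
}

#' Goodness-of-fit balance test against uniform composition
#'
#' An alternative reading of "unbalanced": each group's label counts are
#' tested against equal expected counts (`cell_size / k` per category,
#' df = k - 1), i.e. against a uniform composition rather than against the
#' other group. With unequal true mixing ratios this test has power that
#' grows with cell size, because the null itself is false. Group-level
#' p-values are combined by rule:
#'
#' * `"either"` -- unbalanced if either group rejects (reported p = min),
#' * `"both"` -- unbalanced only if both groups reject (reported p = max),
#' * `"pooled"` -- a single test of the summed composition of both groups.
#'
#' @inheritParams pearson_chi_squared
#' @param combination `"either"`, `"both"` or `"pooled"`.
#' @return A `balance_test_result`; `statistic` and `df` belong to the
#'   group whose p-value is reported (or to the pooled table).
#' @examples
#' goodness_of_fit_uniform(rbind(c(15, 5), c(10, 10)), "either")
#' @export
goodness_of_fit_uniform <- function(table, combination = c("either", "both", "pooled"),
                                    alpha = 0.05) {
  check_table(table)
  combination <- match.arg(combination)
  k <- ncol(table)
  name <- paste0("gof-uniform-", combination)
  if (k == 1L) return(new_balance_result(0, 0L, 1, name, alpha))
  gof <- function(o) {
    e <- sum(o) / k
    sum((o - e)^2 / e)
  }
  df <- k - 1L
  if (combination == "pooled") {
    stat <- gof(colSums(table))
  } else {
    stats2 <- c(gof(table[1L, ]), gof(table[2L, ]))
    p2 <- stats::pchisq(stats2, df, lower.tail = FALSE)
    stat <- if (combination == "either") stats2[which.min(p2)] else stats2[which.max(p2)]
  }
  new_balance_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                     name, alpha)
}

#' Flag a balance-test result as unbalanced
#'
#' Strict threshold: unbalanced iff `p_value < alpha`. A p-value exactly
#' equal to `alpha` is not flagged.
#'
#' @param result a `balance_test_result`.
#' @param alpha threshold in (0, 1), default 0.05.
#' @return Logical.
#' @export
is_unbalanced <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "balance_test_result"),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  result$p_value < alpha
}

#' One-sided (directional) unbalance decision
#'
#' When the study hypothesis predicts a direction, only imbalances favouring
#' the experimental group on a prespecified label can masquerade as the
#' hypothesised effect. This flags a table as hypothesis-relevant unbalanced
#' iff the two-sided test rejects *and* the experimental group holds strictly
#' more `favored_label` members than the control group. Under a symmetric
#' mixture, mirror-image tables are equiprobable, so this halves the
#' unbalanced rate.
#'
#' @param result a two-sided `balance_test_result` for `table`.
#' @param table the 2 x k table the result was computed from.
#' @param favored_label column name whose excess in the experimental group
#'   would mimic the hypothesised effect.
#' @inheritParams is_unbalanced
#' @return Logical.
#' @examples
#' tab <- rbind(c(15, 5), c(5, 15)); colnames(tab) <- c("high", "low")
#' one_sided_unbalanced(pearson_chi_squared(tab), tab, "high")
#' @export
one_sided_unbalanced <- function(result, table, favored_label, alpha = 0.05) {
  check_table(table)
  if (!favored_label %in% colnames(table))
    stop("'favored_label' must be one of: ",
         paste(colnames(table), collapse = ", "), call. = FALSE)
  is_unbalanced(result, alpha) &&
    table[1L, favored_label] > table[2L, favored_label]
}
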