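#' Specify one Monte Carlo scenario
#'
#' A scenario is one cell of the simulation study: a population mixture, a
#' per-group cell size, a number of Monte Carlo draws, the significance
#' threshold, the balance-test variant, the assignment strategy and the RNG
#' seed. The defaults reproduce the reference design: 10,000 draws, alpha
#' 0.05, two-sample chi-squared with continuity correction at df = 1, random
#' assignment.
#'
#' @param mix a [subpop_mix()].
#' @param cell_size subjects per group (>= 2); each draw recruits
#'   `2 * cell_size` subjects.
#' @param draws Monte Carlo replicates (>= 1), default 10000.
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @param variant registered balance-test variant name (see [test_variants()]).
#' @param strategy assignment strategy: `"random"`, `"sequential"`,
#'   `"stratified"` or `"matched"`.
#' @param seed integer RNG seed; the default is a fixed reproducibility
#'   convention.
#' @param rate_means,noise_sd matching-score parameters, used only by the
#'   `"matched"` strategy (see [attach_rate_scores()]).
#' @return A `scenario_spec` list.
#' @examples
#' scenario_spec(study_mixes()[["2-equal"]], cell_size = 20, draws = 1000)
#' @export
scenario_spec <- function(mix, cell_size, draws = 10000, alpha = 0.05,
                          variant = "two-sample-yates", strategy = "random",
                          seed = 20140902, rate_means = NULL, noise_sd = 0.1) {
  stopifnot(inherits(mix, "subpop_mix"))
  if (cell_size < 2) stop("'cell_size' must be >= 2", call. = FALSE)
  if (draws < 1) stop("'draws' must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  get_variant(variant)                     # errors on unknown names
  if (!strategy %in% c("random", "sequential", "stratified", "matched"))
    stop("unknown assignment strategy '", strategy,
         "'; registered strategies: random, sequential, stratified, matched",
         call. = FALSE)
  structure(list(mix = mix, cell_size = as.integer(cell_size),
                 draws = as.integer(draws), alpha = alpha, variant = variant,
                 strategy = strategy, seed = as.integer(seed),
                 rate_means = rate_means, noise_sd = noise_sd),
            class = "scenario_spec")
}

#' Run one Monte Carlo scenario
#'
#' Repeats, `draws` times: recruit a cohort of `2 * cell_size` subjects from
#' the mixture, split it into two groups by the scenario's assignment
#' strategy, cross-tabulate group by subpopulation, and apply the
#' balance-test variant. The unbalanced-sample rate is the fraction of draws
#' with `p < alpha` (strict), reported with its Monte Carlo standard error
#' `sqrt(r * (1 - r) / draws)`. The same seed always reproduces the same
#' result.
#'
#' @param spec a [scenario_spec()].
#' @return A `simulation_result`: list with `unbalanced_rate`, `mc_se`,
#'   `p_values` (length `draws`) and `spec`.
#' @examples
#' res <- run_scenario(scenario_spec(study_mixes()[["2-equal"]], 20,
#'                                   draws = 500, seed = 42))
#' res$unbalanced_rate
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  v <- get_variant(spec$variant)
  k <- length(spec$mix$labels)
  n <- spec$cell_size
  e <- matrix(0L, spec$draws, k)
  f <- matrix(0L, spec$draws, k)
  set.seed(spec$seed)
  for (i in seq_len(spec$draws)) {
    if (spec$strategy == "sequential") {
      drawn <- sequential_split(spec$mix, n)
    } else {
      coh <- sample_cohort(spec$mix, 2L * n)
      if (spec$strategy == "matched")
        coh <- if (is.null(spec$rate_means))
          attach_rate_scores(coh, noise_sd = spec$noise_sd)
        else
          attach_rate_scores(coh, spec$rate_means, spec$noise_sd)
      drawn <- assign_groups(spec$strategy, cohort = coh, cell_size = n)
    }
    e[i, ] <- tabulate(drawn$cohort$subpop[drawn$assignment$experimental], k)
    f[i, ] <- tabulate(drawn$cohort$subpop[drawn$assignment$control], k)
  }
  p_values <- v$pvec(e, f)
  rate <- mean(p_values < spec$alpha)
  structure(list(unbalanced_rate = rate,
                 mc_se = mc_standard_error(rate, spec$draws),
                 p_values = p_values, spec = spec),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Monte Carlo unbalanced-sample rate: %.2f%% (MC SE %.2f%%)\n",
              100 * x$unbalanced_rate, 100 * x$mc_se))
  cat(sprintf("  mix [%s], cell size %d, %d draws, variant %s, strategy %s, alpha %g, seed %d\n",
              paste(sprintf("%s=%g", s$mix$labels, s$mix$proportions),
                    collapse = ", "),
              s$cell_size, s$draws, s$variant, s$strategy, s$alpha, s$seed))
  invisible(x)
}

#' Monte Carlo standard error of a rate estimate
#'
#' @param rate estimated proportion in `[0, 1]`.
#' @param draws number of Monte Carlo draws.
#' @return `sqrt(rate * (1 - rate) / draws)`.
#' @examples
#' mc_standard_error(0.0174, 10000)
#' @export
mc_standard_error <- function(rate, draws) {
  stopifnot(rate >= 0, rate <= 1, draws >= 1)
  sqrt(rate * (1 - rate) / draws)
}

#' Histogram of per-draw p-values
#'
#' Bins the scenario's p-values into a partition of `[0, 1]`. Bins are
#' half-open `[lo, hi)` except the last, which is closed so that p = 1 is
#' counted. With 0.05 as a bin edge, the mass strictly below 0.05 equals the
#' unbalanced count exactly.
#'
#' @param result a [run_scenario()] result.
#' @param bins increasing numeric vector of bin edges from 0 to 1
#'   (default 20 bins of width 0.05).
#' @return A data.frame with columns `bin_lo`, `bin_hi`, `count`; counts sum
#'   to `draws`.
#' @export
pvalue_histogram <- function(result, bins = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(result, "simulation_result"))
  if (length(bins) < 2L || is.unsorted(bins, strictly = TRUE) ||
      abs(bins[1L]) > 1e-12 || abs(bins[length(bins)] - 1) > 1e-12)
    stop("'bins' must be a strictly increasing partition of [0, 1]",
         call. = FALSE)
  idx <- findInterval(result$p_values, bins, rightmost.closed = TRUE)
  data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1L],
             count = tabulate(idx, length(bins) - 1L))
}

#' Run the full scenario suite
#'
#' Runs every reference mixture ([study_mixes()]) at each requested cell
#' size and tabulates the unbalanced-sample rates in the reporting format of
#' the reference study (percentages to two decimals), alongside the
#' full-precision rates and their Monte Carlo standard errors. Per-scenario
#' seeds are `seed + 1, seed + 2, ...` in row order.
#'
#' @param cell_sizes integer vector of per-group sizes, default `c(20, 40)`.
#' @inheritParams scenario_spec
#' @return A data.frame with one row per mix x cell size; the full
#'   [run_scenario()] results are attached as `attr(, "results")`.
#' @examples
#' \donttest{
#' scenario_suite(draws = 1000, seed = 7)
#' }
#' @export
scenario_suite <- function(cell_sizes = c(20, 40), variant = "two-sample-yates",
                           strategy = "random", draws = 10000, alpha = 0.05,
                           seed = 20140902) {
  mixes <- study_mixes()
  grid <- expand.grid(mix = names(mixes), cell_size = cell_sizes,
                      stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mx <- mixes[[grid$mix[i]]]
    spec <- scenario_spec(mx, grid$cell_size[i], draws = draws, alpha = alpha,
                          variant = variant, strategy = strategy,
                          seed = seed + i)
    results[[i]] <- run_scenario(spec)
    rows[[i]] <- data.frame(
      mix = grid$mix[i],
      ratios = paste(sprintf("%g", round(100 * mx$proportions, 2)),
                     collapse = "/"),
      cell_size = grid$cell_size[i], variant = variant, strategy = strategy,
      draws = draws, alpha = alpha, seed = seed + i,
      unbalanced_rate = results[[i]]$unbalanced_rate,
      mc_se = results[[i]]$mc_se,
      percent = round(100 * results[[i]]$unbalanced_rate, 2))
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}

#' Reference unbalanced-sample percentages
#'
#' The unbalanced-sample percentages reported by the original published
#' 10,000-draw Monte Carlo study of this design, one per reference mixture
#' and cell size. They are the calibration targets for
#' [calibrate_variants()] and the comparison points for the reproduction
#' scenarios; they are inputs, not outputs, of this package.
#'
#' @return A data.frame with columns `mix`, `cell_size`, `percent`.
#' @export
reference_rates <- function() {
  data.frame(
    mix = rep(c("2-equal", "3-equal", "2-unequal", "3-unequal"), 2),
    cell_size = rep(c(20L, 40L), each = 4),
    percent = c(1.74, 5.18, 4.23, 37.87,
                3.47, 5.20, 11.05, 69.47)
  )
}
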