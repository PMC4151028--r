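#' Assignment strategies: splitting a cohort into experimental and control
#'
#' Four strategies split a recruited cohort into two groups of equal size
#' `cell_size`:
#'
#' * `random_split()` -- the standard design: a uniformly random partition of
#'   the cohort into two groups of `cell_size` (every one of the
#'   `choose(2n, n)` partitions is equally likely).
#' * `sequential_split()` -- assignment at the recruiting stage: subjects are
#'   sampled from the mix one at a time and sent to a group by fair coin
#'   until one group fills; the remainder go to the other group. Under
#'   i.i.d. sampling this is distributionally identical to recruiting
#'   everyone first and using `random_split()`.
#' * `stratified_split()` -- a remedy: within each subpopulation, members are
#'   divided as evenly as possible between the groups (per-label counts
#'   differ by at most 1), which caps the achievable chi-squared statistic
#'   near zero at realistic cell sizes.
#' * `matched_pairs_split()` -- a remedy usable when subpopulation membership
#'   is latent but a rate score has been measured
#'   ([attach_rate_scores()]): subjects are sorted by score, adjacent ranks
#'   are paired, and one member of each pair goes to each group at random.
#'
#' @param cohort a [sample_cohort()] result of size `2 * cell_size`.
#' @param cell_size subjects per group.
#' @param mix for `sequential_split()`, the [subpop_mix()] to recruit from.
#' @return A `group_assignment`: list with integer index vectors
#'   `experimental` and `control` (disjoint, covering all cohort indices,
#'   each of length `cell_size`) and the `strategy` name.
#'   `sequential_split()` returns a list with elements `cohort` and
#'   `assignment`, since it recruits and assigns in one pass.
#' @examples
#' set.seed(1)
#' coh <- sample_cohort(study_mixes()[["2-equal"]], 40)
#' a <- random_split(coh, 20)
#' build_table(a, coh)
#' @name assignment
NULL

new_assignment <- function(experimental, control, strategy) {
  structure(list(experimental = as.integer(experimental),
                 control = as.integer(control),
                 strategy = strategy),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Group assignment (", x$strategy, "): ",
      length(x$experimental), " experimental vs ",
      length(x$control), " control\n", sep = "")
  invisible(x)
}

check_split_sizes <- function(cohort, cell_size) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(cell_size) != 1L || is.na(cell_size) || cell_size < 1)
    stop("'cell_size' must be a positive integer", call. = FALSE)
  if (length(cohort) != 2 * cell_size)
    stop(sprintf("cohort has %d subjects but 2 * cell_size = %d are required",
                 length(cohort), 2 * cell_size), call. = FALSE)
}

#' @rdname assignment
#' @export
random_split <- function(cohort, cell_size) {
  check_split_sizes(cohort, cell_size)
  idx <- sample.int(2L * cell_size, cell_size)
  new_assignment(idx, setdiff(seq_len(2L * cell_size), idx), "random")
}

#' @rdname assignment
#' @export
sequential_split <- function(mix, cell_size) {
  stopifnot(inherits(mix, "subpop_mix"))
  if (length(cell_size) != 1L || is.na(cell_size) || cell_size < 1)
    stop("'cell_size' must be a positive integer", call. = FALSE)
  n_total <- 2L * cell_size
  codes <- integer(n_total)
  groups <- integer(n_total)      # 1 = experimental, 2 = control
  filled <- c(0L, 0L)
  k <- length(mix$labels)
  for (i in seq_len(n_total)) {
    codes[i] <- sample.int(k, 1L, prob = mix$proportions)
    g <- if (filled[1L] >= cell_size) 2L
         else if (filled[2L] >= cell_size) 1L
         else sample.int(2L, 1L)
    groups[i] <- g
    filled[g] <- filled[g] + 1L
  }
  list(cohort = new_cohort(codes, NULL, mix),
       assignment = new_assignment(which(groups == 1L), which(groups == 2L),
                                   "sequential"))
}

#' @rdname assignment
#' @export
stratified_split <- function(cohort, cell_size) {
  check_split_sizes(cohort, cell_size)
  counts <- cohort_counts(cohort)
  odd <- which(counts %% 2L == 1L)
  # per even stratum: half to each group; odd strata (always an even number
  # of them, since counts sum to 2*cell_size) are randomly paired off so
  # that exactly half send their extra member to the experimental group
  extra_to_exp <- rep(FALSE, length(counts))
  if (length(odd)) {
    if (length(odd) %% 2L != 0L)
      stop("infeasible stratified rounding: odd strata do not pair up ",
           "(group sizes cannot both equal cell_size)", call. = FALSE)
    extra_to_exp[sample(odd, length(odd) / 2L)] <- TRUE
  }
  experimental <- integer(0)
  for (j in seq_along(counts)) {
    members <- which(cohort$subpop == j)
    if (!length(members)) next
    take <- counts[j] %/% 2L + (counts[j] %% 2L) * extra_to_exp[j]
    experimental <- c(experimental,
                      members[sample.int(length(members), take)])
  }
  if (length(experimental) != cell_size)
    stop("infeasible stratified rounding: could not reach exact group sizes",
         call. = FALSE)
  new_assignment(sort(experimental),
                 setdiff(seq_len(2L * cell_size), experimental), "stratified")
}

#' @rdname assignment
#' @export
matched_pairs_split <- function(cohort, cell_size) {
  check_split_sizes(cohort, cell_size)
  if (is.null(cohort$rate_score))
    stop("matched-pair assignment needs rate scores; call attach_rate_scores() first",
         call. = FALSE)
  ord <- order(cohort$rate_score)      # stable; ties keep recruitment order
  first_of_pair <- stats::runif(cell_size) < 0.5
  pick <- ifelse(first_of_pair, seq(1L, 2L * cell_size, by = 2L),
                 seq(2L, 2L * cell_size, by = 2L))
  experimental <- ord[pick]
  new_assignment(sort(experimental),
                 setdiff(seq_len(2L * cell_size), experimental), "matched")
}

#' Run an assignment strategy by name
#'
#' Dispatches to one of the strategy functions; `"sequential"` recruits its
#' own cohort from `mix` and ignores `cohort`.
#'
#' @param strategy one of `"random"`, `"sequential"`, `"stratified"`,
#'   `"matched"`.
#' @inheritParams assignment
#' @return A list with elements `cohort` and `assignment`.
#' @export
assign_groups <- function(strategy, cohort = NULL, mix = NULL, cell_size) {
  switch(strategy,
    random     = list(cohort = cohort,
                      assignment = random_split(cohort, cell_size)),
    sequential = sequential_split(mix, cell_size),
    stratified = list(cohort = cohort,
                      assignment = stratified_split(cohort, cell_size)),
    matched    = list(cohort = cohort,
                      assignment = matched_pairs_split(cohort, cell_size)),
    stop("unknown assignment strategy '", strategy,
         "'; registered strategies: random, sequential, stratified, matched",
         call. = FALSE)
  )
}
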