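#' Recruit a cohort by random sampling from a population mixture
#'
#' Draws `size` subjects i.i.d. from the mixture: each subject's
#' subpopulation label is sampled independently with probabilities equal to
#' the mix proportions (an infinite-population model -- recruiting does not
#' deplete the population). The cohort is later split into two equal groups,
#' so `size` must be even; a study with `n` subjects per cell recruits
#' `size = 2 * n`.
#'
#' @param mix a [subpop_mix()].
#' @param size even integer >= 2, total number of subjects recruited.
#' @return An object of class `cohort`: a list with `subpop` (integer codes
#'   into `mix$labels`), `rate_score` (numeric or `NULL`, see
#'   [attach_rate_scores()]) and `mix`.
#' @examples
#' set.seed(1)
#' coh <- sample_cohort(subpop_mix(c("high", "low"), c(0.5, 0.5)), 40)
#' table(cohort_labels(coh))
#' @export
sample_cohort <- function(mix, size) {
  stopifnot(inherits(mix, "subpop_mix"))
  if (length(size) != 1L || is.na(size) || size < 2 || size %% 2 != 0)
    stop("'size' must be a positive even integer (two equal groups are formed downstream)",
         call. = FALSE)
  codes <- sample.int(length(mix$labels), size, replace = TRUE,
                      prob = mix$proportions)
  new_cohort(codes, NULL, mix)
}

new_cohort <- function(subpop, rate_score, mix) {
  structure(list(subpop = as.integer(subpop), rate_score = rate_score,
                 mix = mix),
            class = "cohort")
}

#' Subject labels of a cohort
#'
#' @param cohort a [sample_cohort()] result.
#' @return Character vector of subpopulation labels, one per subject, in
#'   recruitment order.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$mix$labels[cohort$subpop]
}

#' Per-label subject counts of a cohort
#'
#' @param cohort a [sample_cohort()] result.
#' @return Integer vector of counts, named by label, in mix label order
#'   (zero-count labels included).
#' @export
cohort_counts <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  stats::setNames(tabulate(cohort$subpop, length(cohort$mix$labels)),
                  cohort$mix$labels)
}

#' @export
length.cohort <- function(x) length(x$subpop)

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort of ", length(x), " subjects (",
      if (is.null(x$rate_score)) "no" else "with", " rate scores)\n", sep = "")
  print(cohort_counts(x))
  invisible(x)
}

#' Attach latent learning-rate scores to a cohort
#'
#' Gives each subject a measured rate-of-improvement score: the mean score of
#' its subpopulation plus zero-mean Gaussian measurement noise. With
#' `noise_sd = 0` scores equal the subpopulation means exactly. Scores are
#' the matching variable for [matched_pairs_split()]; they play no role in
#' the balance test itself, which uses subpopulation labels only.
#'
#' @param cohort a [sample_cohort()] result.
#' @param rate_means named numeric vector covering every label in the
#'   cohort's mix (arbitrary units). Defaults: high = 1.0, medium = 0.6,
#'   low = 0.2 for the standard label sets.
#' @param noise_sd non-negative measurement noise standard deviation
#'   (same units as `rate_means`; default 0.1).
#' @return The cohort with `rate_score` filled in.
#' @examples
#' set.seed(1)
#' coh <- sample_cohort(study_mixes()[["3-equal"]], 10)
#' attach_rate_scores(coh, noise_sd = 0)$rate_score
#' @export
attach_rate_scores <- function(cohort,
                               rate_means = default_rate_means(cohort$mix),
                               noise_sd = 0.1) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be a single non-negative number", call. = FALSE)
  missing <- setdiff(cohort$mix$labels, names(rate_means))
  if (length(missing))
    stop("'rate_means' is missing labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  mu <- as.numeric(rate_means[cohort_labels(cohort)])
  cohort$rate_score <- mu + stats::rnorm(length(cohort), 0, noise_sd)
  cohort
}

default_rate_means <- function(mix) {
  base <- c(high = 1.0, medium = 0.6, low = 0.2)
  if (all(mix$labels %in% names(base))) return(base[mix$labels])
  # arbitrary mixes: evenly spaced means in label order
  stats::setNames(seq(1, 0.2, length.out = length(mix$labels)), mix$labels)
}
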