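# Independent brute-force re-derivations used as oracles against the
# package's closed-form / vectorised implementations.

# Pearson statistic by explicit double loop over cells, margins-based
# expected counts; no zero-column handling (callers supply positive margins).
brute_force_chisq <- function(tab, correction = FALSE) {
  n <- sum(tab)
  stat <- 0
  yates <- if (correction) {
    devs <- abs(tab - outer(rowSums(tab), colSums(tab)) / n)
    min(0.5, devs)
  } else 0
  for (g in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rowSums(tab)[g] * colSums(tab)[j] / n
      stat <- stat + (abs(tab[g, j] - e) - yates)^2 / e
    }
  }
  stat
}

# random 2 x k table with strictly positive column margins and equal row sums
random_table <- function(k, n) {
  repeat {
    e <- as.vector(stats::rmultinom(1, n, rep(1 / k, k)))
    f <- as.vector(stats::rmultinom(1, n, rep(1 / k, k)))
    tab <- rbind(e, f)
    if (all(colSums(tab) > 0)) {
      colnames(tab) <- paste0("s", seq_len(k))
      return(tab)
    }
  }
}

mix2 <- function() subpop_mix(c("high", "low"), c(0.5, 0.5))
mix3 <- function() subpop_mix(c("high", "medium", "low"), rep(1 / 3, 3))

# deterministic cohort with given per-label counts, in label order
fixed_cohort <- function(counts, mix) {
  structure(list(subpop = as.integer(rep(seq_along(counts), counts)),
                 rate_score = NULL, mix = mix),
            class = "cohort")
}
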