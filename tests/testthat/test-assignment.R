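expect_valid_partition <- function(a, n_total, cell_size) {
  expect_length(a$experimental, cell_size)
  expect_length(a$control, cell_size)
  expect_length(intersect(a$experimental, a$control), 0)
  expect_setequal(c(a$experimental, a$control), seq_len(n_total))
}

test_that("every strategy yields a disjoint, exhaustive, exact-size partition", {
  set.seed(31)
  for (mix in list(mix2(), mix3())) {
    for (cell in c(5, 20)) {
      coh <- sample_cohort(mix, 2 * cell)
      scored <- attach_rate_scores(coh)
      expect_valid_partition(random_split(coh, cell), 2 * cell, cell)
      expect_valid_partition(stratified_split(coh, cell), 2 * cell, cell)
      expect_valid_partition(matched_pairs_split(scored, cell), 2 * cell, cell)
      seq_res <- sequential_split(mix, cell)
      expect_valid_partition(seq_res$assignment, 2 * cell, cell)
      expect_length(seq_res$cohort, 2 * cell)
    }
  }
  expect_error(random_split(sample_cohort(mix2(), 40), 15), "2 \\* cell_size")
})

test_that("random_split is uniform over partitions (hypergeometric checks)", {
  # 2 highs among 40: both land in the same group with probability 19/39
  coh <- fixed_cohort(c(2, 38), mix2())
  set.seed(41)
  R <- 4000
  same <- replicate(R, {
    tab <- build_table(random_split(coh, 20), coh)
    tab["experimental", "high"] %in% c(0L, 2L)
  })
  p <- 19 / 39
  expect_lt(abs(mean(same) - p), 3 * sqrt(p * (1 - p) / R))

  # cohort of 4 (2 high, 2 low): P(experimental = both highs) = 1/6
  tiny <- fixed_cohort(c(2, 2), mix2())
  set.seed(42)
  both <- replicate(R, {
    tab <- build_table(random_split(tiny, 2), tiny)
    tab["experimental", "high"] == 2L
  })
  expect_lt(abs(mean(both) - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / R))
})

test_that("sequential assignment matches recruit-all-then-split in distribution", {
  base <- scenario_spec(mix2(), 20, draws = 10000, seed = 505)
  r_random <- run_scenario(base)
  r_seq <- run_scenario(scenario_spec(mix2(), 20, draws = 10000,
                                      strategy = "sequential", seed = 606))
  pooled_se <- sqrt(r_random$mc_se^2 + r_seq$mc_se^2)
  expect_lt(abs(r_random$unbalanced_rate - r_seq$unbalanced_rate),
            3 * pooled_se)
})

test_that("stratified splits divide each stratum as evenly as possible", {
  even <- fixed_cohort(c(20, 20), mix2())
  set.seed(51)
  tab <- build_table(stratified_split(even, 20), even)
  expect_equal(unname(tab), rbind(c(10, 10), c(10, 10)))

  odd <- fixed_cohort(c(21, 19), mix2())
  for (i in 1:20) {
    tab <- build_table(stratified_split(odd, 20), odd)
    expect_equal(unname(rowSums(tab)), c(20, 20))
    expect_equal(abs(tab[1, ] - tab[2, ]), c(high = 1, low = 1))
  }

  # balance guarantee: stratified tables are never flagged
  set.seed(52)
  for (i in 1:200) {
    coh <- sample_cohort(mix3(), 40)
    res <- pearson_chi_squared(build_table(stratified_split(coh, 20), coh))
    expect_gt(res$p_value, 0.05)
  }
})

test_that("matched pairs pair adjacent ranks and bound group score difference", {
  coh <- fixed_cohort(c(2, 2), mix2())
  coh$rate_score <- c(3, 1, 4, 2)   # ranks: subj 2,4,1,3
  set.seed(61)
  for (i in 1:20) {
    a <- matched_pairs_split(coh, 2)
    # pairs by rank: {2,4} (scores 1,2) and {1,3} (scores 3,4)
    expect_length(intersect(a$experimental, c(2, 4)), 1)
    expect_length(intersect(a$experimental, c(1, 3)), 1)
  }

  expect_error(matched_pairs_split(fixed_cohort(c(2, 2), mix2()), 2),
               "rate scores")

  set.seed(62)
  for (i in 1:50) {
    scored <- attach_rate_scores(sample_cohort(mix3(), 40), noise_sd = 0.1)
    a <- matched_pairs_split(scored, 20)
    s <- sort(scored$rate_score)
    max_gap <- max(s[seq(2, 40, 2)] - s[seq(1, 40, 2)])
    diff <- abs(mean(scored$rate_score[a$experimental]) -
                mean(scored$rate_score[a$control]))
    expect_lte(diff, max_gap + 1e-12)
  }
})

test_that("noise-free matched pairs reproduce stratified balance for two subpopulations", {
  set.seed(71)
  for (i in 1:100) {
    counts <- c(h <- sample(0:12, 1), 12 - h)
    coh <- fixed_cohort(counts, mix2())
    coh <- attach_rate_scores(coh, c(high = 1.0, low = 0.2), noise_sd = 0)
    tab <- build_table(matched_pairs_split(coh, 6), coh)
    expect_true(all(abs(tab[1, ] - tab[2, ]) <= 1))
  }
  # with three subpopulations a label can straddle two pairs: bound is 2
  set.seed(72)
  for (i in 1:50) {
    coh <- attach_rate_scores(sample_cohort(mix3(), 12), noise_sd = 0)
    tab <- build_table(matched_pairs_split(coh, 6), coh)
    expect_true(all(abs(tab[1, ] - tab[2, ]) <= 2))
  }
})

test_that("unknown strategies are rejected with the registered list", {
  expect_error(assign_groups("adaptive", cohort = fixed_cohort(c(2, 2), mix2()),
                             cell_size = 2),
               "random, sequential, stratified, matched")
})
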