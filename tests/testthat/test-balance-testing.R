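test_that("contingency tables cross-tabulate group by subpopulation", {
  coh <- fixed_cohort(c(20, 20), mix2())
  a <- structure(list(experimental = 1:20, control = 21:40,
                      strategy = "manual"), class = "group_assignment")
  tab <- build_table(a, coh)
  expect_equal(unname(tab), rbind(c(20, 0), c(0, 20)))
  expect_equal(colnames(tab), c("high", "low"))

  b <- structure(list(experimental = c(1:15, 21:25), control = c(16:20, 26:40),
                      strategy = "manual"), class = "group_assignment")
  expect_equal(unname(build_table(b, coh)), rbind(c(15, 5), c(5, 15)))

  # conservation: column sums equal cohort label counts for any assignment
  set.seed(81)
  coh <- sample_cohort(mix3(), 30)
  for (i in 1:10) {
    tab <- build_table(random_split(coh, 15), coh)
    expect_equal(colSums(tab), cohort_counts(coh))
  }
})

test_that("Pearson statistics match hand-computed closed forms", {
  sym <- rbind(c(10, 10), c(10, 10))
  res <- pearson_chi_squared(sym)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  skewed <- rbind(c(15, 5), c(5, 15))
  # closed forms: N(ad-bc)^2/(r1 r2 c1 c2) and Yates N(|ad-bc|-N/2)^2/(...)
  plain <- pearson_chi_squared(skewed, correction = FALSE)
  expect_equal(plain$statistic, 10.0)
  expect_equal(plain$df, 1L)
  expect_equal(plain$p_value, 0.001565, tolerance = 1e-3)
  yates <- pearson_chi_squared(skewed, correction = TRUE)
  expect_equal(yates$statistic, 8.1)
  expect_equal(yates$p_value, 0.00443, tolerance = 1e-3)

  # all-zero column dropped, df reduces to 1, correction reapplies
  padded <- rbind(c(12, 8, 0), c(8, 12, 0))
  expect_equal(pearson_chi_squared(padded, correction = FALSE)$statistic, 1.6)
  expect_equal(pearson_chi_squared(padded, correction = FALSE)$p_value,
               0.2059, tolerance = 1e-3)
  expect_equal(pearson_chi_squared(padded)$statistic, 0.9)
  expect_equal(pearson_chi_squared(padded)$p_value, 0.3428, tolerance = 1e-3)

  # degenerate single-column table is balanced by convention
  degen <- pearson_chi_squared(rbind(5L, 5L))
  expect_equal(degen$p_value, 1)
  expect_false(degen$unbalanced)
  expect_error(pearson_chi_squared(matrix(nrow = 2, ncol = 0)), "2 x k")
})

test_that("statistics agree with stats::chisq.test and a brute-force oracle", {
  set.seed(91)
  for (i in 1:150) {
    k <- sample(2:3, 1)
    tab <- random_table(k, 20)
    for (corr in c(FALSE, TRUE)) {
      mine <- pearson_chi_squared(tab, correction = corr)
      ref <- suppressWarnings(stats::chisq.test(tab, correct = corr))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter))
      expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
      expect_lt(abs(mine$statistic - brute_force_chisq(tab, corr && k == 2)),
                1e-10)
    }
  }
})

test_that("correction never increases the statistic; tests are symmetric", {
  set.seed(92)
  for (i in 1:100) {
    tab <- random_table(sample(2:3, 1), 20)
    expect_lte(pearson_chi_squared(tab, TRUE)$statistic,
               pearson_chi_squared(tab, FALSE)$statistic)
    # row swap and column permutation invariance
    perm <- sample(ncol(tab))
    expect_equal(pearson_chi_squared(tab)$statistic,
                 pearson_chi_squared(tab[2:1, perm])$statistic,
                 tolerance = 1e-12)
  }
})

test_that("goodness-of-fit variant tests groups against uniform composition", {
  exact_fit <- goodness_of_fit_uniform(rbind(c(10, 10), c(10, 10)), "either")
  expect_equal(exact_fit$statistic, 0)
  expect_equal(exact_fit$p_value, 1)

  one_off <- goodness_of_fit_uniform(rbind(c(15, 5), c(10, 10)), "either")
  expect_equal(one_off$statistic, 5.0)   # (25 + 25) / 10
  expect_equal(one_off$df, 1L)
  expect_equal(one_off$p_value, 0.0253, tolerance = 1e-2)
  expect_equal(one_off$p_value,
               suppressWarnings(chisq.test(c(15, 5), p = c(.5, .5))$p.value),
               tolerance = 1e-12)

  pooled <- goodness_of_fit_uniform(rbind(c(15, 5), c(10, 10)), "pooled")
  expect_equal(pooled$statistic, (25 + 25) / 20)

  # "both" can never flag when "either" does not
  set.seed(93)
  for (i in 1:100) {
    tab <- random_table(sample(2:3, 1), 20)
    both <- goodness_of_fit_uniform(tab, "both")$unbalanced
    either <- goodness_of_fit_uniform(tab, "either")$unbalanced
    expect_true(!both || either)
  }
})

test_that("the unbalanced flag uses a strict threshold", {
  fake <- function(p) structure(list(statistic = 1, df = 1L, p_value = p,
                                     variant = "x", alpha = 0.05,
                                     unbalanced = p < 0.05),
                                class = "balance_test_result")
  expect_true(is_unbalanced(fake(0.0499), 0.05))
  expect_false(is_unbalanced(fake(0.05), 0.05))
  expect_false(is_unbalanced(fake(1), 0.9))
  expect_error(is_unbalanced(fake(0.5), 1.5))
})

test_that("one-sided decisions require a directional excess", {
  tab <- rbind(c(15, 5), c(5, 15)); colnames(tab) <- c("high", "low")
  res <- pearson_chi_squared(tab)
  expect_true(one_sided_unbalanced(res, tab, "high"))

  mirror <- tab[2:1, ]
  expect_false(one_sided_unbalanced(pearson_chi_squared(mirror), mirror, "high"))
  expect_error(one_sided_unbalanced(res, tab, "medium"), "must be one of")
})

test_that("variant registry dispatches by name and rejects unknown names", {
  expect_setequal(test_variants(),
                  c("two-sample-yates", "two-sample", "gof-uniform-either",
                    "gof-uniform-both", "gof-uniform-pooled",
                    "two-sample-yates-directional"))
  expect_error(get_variant("fisher"), "two-sample-yates")

  # scalar table functions agree with the vectorised kernels used by the
  # engine and oracle
  set.seed(94)
  for (i in 1:60) {
    k <- sample(2:3, 1)
    e <- as.vector(rmultinom(1, 20, rep(1 / k, k)))
    f <- as.vector(rmultinom(1, 20, rep(1 / k, k)))
    tab <- rbind(e, f)
    colnames(tab) <- paste0("s", 1:k)
    for (v in test_variants()) {
      scalar <- apply_variant(v, tab)$p_value
      vec <- get_variant(v)$pvec(matrix(e, 1), matrix(f, 1))
      expect_equal(scalar, vec, tolerance = 1e-12)
    }
  }
})
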