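test_that("Mann-Whitney comparison matches exact enumeration on small samples", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, enumerate_mw_p(c(1, 2, 3), c(4, 5, 6)))
  # a second, non-extreme configuration against the enumeration oracle
  a <- c(1.2, 3.4, 5.1, 0.4)
  b <- c(2.2, 6.5, 7.1)
  expect_equal(compare_groups(a, b)$p_value, enumerate_mw_p(a, b),
               tolerance = 1e-12)
})

test_that("group comparison is symmetric and handles degenerate inputs", {
  a <- c(0.1, 0.9, 0.4, 0.7)
  b <- c(0.2, 0.3, 1.5)
  expect_equal(compare_groups(a, b)$p_value, compare_groups(b, a)$p_value)
  expect_equal(compare_groups(5, 5)$p_value, 1.0)
  expect_equal(compare_groups(rep(2, 4), rep(2, 6))$p_value, 1.0)
  expect_error(compare_groups(numeric(0), 1), "nonempty")
})

test_that("Kruskal-Wallis matches the direct H formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(groups)
  oracle <- direct_kw(groups)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-9)
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-9)
  # with ties
  groups2 <- list(c(1, 1, 2.5), c(2.5, 4), c(4, 4, 6))
  res2 <- kruskal_wallis(groups2)
  oracle2 <- direct_kw(groups2)
  expect_equal(res2$statistic, oracle2$statistic, tolerance = 1e-9)
  expect_equal(res2$p_value, oracle2$p_value, tolerance = 1e-9)
})

test_that("Kruskal-Wallis on identical groups reports no evidence of difference", {
  res <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1.0)
  expect_error(kruskal_wallis(list(c(1, 2))), "at least 2")
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "nonempty")
})

test_that("Kruskal-Wallis null rejection rate is near nominal", {
  set.seed(420)
  n_reps <- 2000
  rej <- 0
  for (r in seq_len(n_reps)) {
    g <- list(rnorm(10), rnorm(10), rnorm(10))
    if (kruskal_wallis(g)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_reps, 0.035)
  expect_lt(rej / n_reps, 0.07)
})

test_that("phenotype-covariate association splits the covariate by presence", {
  res <- association_with_covariate(c(TRUE, TRUE, FALSE, FALSE),
                                    c(1, 2, 9, 10))
  expect_equal(res$statistic, 0)  # complete separation
  expect_equal(association_with_covariate(c(TRUE, FALSE, TRUE),
                                          c(3, 3, 3))$p_value, 1.0)
  expect_error(association_with_covariate(rep(TRUE, 3), 1:3), "classes")
  expect_error(association_with_covariate(c(TRUE, FALSE), 1:3), "length")
})

test_that("bootstrap sufficiency reproduces the exact small-sample expectation", {
  pool <- rep(c("CARDIAC", "SPECIALIZED"), each = 50)
  # size-2 resample: P(both same) = 1/2 -> H = 0, else H = ln 2;
  # E[H] = 0.5 * ln 2 (exact enumeration over the 4 equally likely draws)
  curve <- bootstrap_sufficiency(pool, sample_sizes = 2, n_reps = 4000,
                                 seed = 11)
  expect_lt(abs(curve$mean_shannon - 0.5 * log(2)), 3 * curve$se_shannon)
})

test_that("bootstrap curve is nondecreasing in sample size and biased downward at full size", {
  pool <- rep(c("CARDIAC", "SPECIALIZED"), each = 50)
  curve <- bootstrap_sufficiency(pool, sample_sizes = c(2, 4, 8, 16, 32, 100),
                                 n_reps = 2000, seed = 7)
  steps <- diff(curve$mean_shannon)
  step_se <- sqrt(curve$se_shannon[-1]^2 + curve$se_shannon[-nrow(curve)]^2)
  expect_true(all(steps > -3 * step_se))
  # resampling bias is downward: at the population size the bootstrap mean
  # cannot exceed the population Shannon index (ln 2 here)
  expect_lte(curve$mean_shannon[curve$sample_size == 100], log(2))
})

test_that("bootstrap is reproducible from its seed and validates inputs", {
  pool <- rep(c("CARDIAC", "SPECIALIZED", "MATURE_INTESTINAL"), c(5, 3, 2))
  c1 <- bootstrap_sufficiency(pool, c(2, 5), n_reps = 50, seed = 99)
  c2 <- bootstrap_sufficiency(pool, c(2, 5), n_reps = 50, seed = 99)
  expect_identical(c1, c2)
  expect_equal(bootstrap_sufficiency(rep("CARDIAC", 10), c(2, 5),
                                     n_reps = 20, seed = 1)$mean_shannon,
               c(0, 0))
  expect_error(bootstrap_sufficiency(pool, c(2, 5), n_reps = 50), "seed")
  expect_error(bootstrap_sufficiency(pool, 0, n_reps = 5, seed = 1), ">= 1")
})
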