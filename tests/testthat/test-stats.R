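test_that("mean and SEM follow the reporting convention", {
  ms <- mean_sem(c(2, 4, 6))
  expect_equal(ms$mean, 4)
  expect_equal(ms$sem, sd(c(2, 4, 6)) / sqrt(3))
  expect_true(is.na(mean_sem(5)$sem))
  expect_equal(mean_sem(rep(3, 4))$sem, 0)
  expect_error(mean_sem(numeric(0)), class = "invalid_spec")
})

test_that("well-separated groups earn three stars after Bonferroni", {
  set.seed(21)
  a <- rnorm(8, 0, 1); b <- rnorm(8, 10, 1)   # ~10 pooled SDs apart
  res <- anova_bonferroni(list(ctl = a, high = b, mid = rnorm(8, 5, 1)))
  pw <- res$pairwise
  row <- pw[pw$group_a == "ctl" & pw$group_b == "high", ]
  expect_lt(row$p_adjusted, 0.001)
  expect_identical(row$stars, "***")
})

test_that("Bonferroni-adjusted p is never below the raw p", {
  set.seed(31)
  for (i in 1:10) {
    gr <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6), d = rnorm(6))
    pw <- anova_bonferroni(gr)$pairwise
    expect_true(all(pw$p_adjusted >= pw$p_raw))
    expect_true(all(pw$p_adjusted <= 1 & pw$p_raw >= 0))
  }
})

test_that("two-group ANOVA agrees with the pooled t test (F = t^2)", {
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(7, 0, 1); b <- rnorm(9, 0.8, 1.3)
    res <- anova_bonferroni(list(a = a, b = b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("groups that are too small are rejected by name", {
  expect_error(anova_bonferroni(list(a = 1:3, tiny = 5)), "tiny",
               class = "invalid_spec")
})

test_that("Mann-Whitney exact path matches full enumeration", {
  # fully separated groups: extreme U, smallest exact two-sided p = 2/20
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_true(res$statistic %in% c(0, 9))
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
  # random tie-free small samples vs full enumeration (n <= 8 per group)
  set.seed(51)
  for (i in 1:8) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    v <- sample(1000, na + nb)      # distinct -> tie-free
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    expect_equal(mann_whitney(a, b)$p_value, mw_enumerate_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles ties, symmetry, and identical groups", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  a <- c(3, 1, 4, 1, 5); b <- c(9, 2, 6, 5)
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)
  allsame <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_true(allsame$tied)
  expect_equal(allsame$p_value, 1)
})

test_that("stars are monotone in the adjusted p-value", {
  expect_identical(significance_stars(c(2e-4, 2e-3, 2e-2, 0.2)),
                   c("***", "**", "*", "ns"))
})

test_that("the test chooser prefers ANOVA only for large normal groups", {
  set.seed(61)
  big <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_match(compare_groups(big)$test, "ANOVA")
  small <- list(a = rnorm(3), b = rnorm(3))
  expect_match(compare_groups(small)$test, "Mann-Whitney")
})
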