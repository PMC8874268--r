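as_log <- function(ids) tibble::tibble(image_id = ids)

test_that("switch and unique counts enumerate adjacent pairs and distinct ids", {
  expect_equal(count_switches(as_log(c("A", "A", "A"))), 0)
  expect_equal(count_switches(as_log(c("A", "A", "B", "A"))), 2)
  expect_equal(unique_images(as_log(c("A", "A", "A"))), 1)
  expect_equal(unique_images(as_log(c("A", "A", "B", "A"))), 2)
  # all-distinct log of length k
  expect_equal(count_switches(as_log(letters[1:7])), 6)
  expect_error(count_switches(as_log(character(0))), "empty")
  expect_error(unique_images(as_log(character(0))), "empty")
})

test_that("unique_images never exceeds total_switches + 1", {
  set.seed(77)
  for (i in 1:25) {
    ids <- sample(letters[1:4], sample(1:40, 1), replace = TRUE)
    expect_lte(unique_images(as_log(ids)), count_switches(as_log(ids)) + 1)
    expect_equal(unique_images(as_log(ids)), length(unique(ids)))
  }
})

test_that("exact rank-sum p-values match hand enumeration", {
  # complete separation: the one most extreme labeling out of C(6,3) = 20
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 20)
  expect_equal(res$statistic, 6)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3),
                                 alternative = "greater")$p_value, 1 / 20)
  # identical multisets: everything is as extreme as observed
  expect_equal(wilcoxon_rank_sum(c(2, 4, 9), c(2, 4, 9))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals brute force over all 924 splits and wilcox.test", {
  set.seed(31)
  for (rep in 1:3) {
    x <- sample(1:50, 6)
    y <- sample(51:100, 6) - 50 + rnorm(6, 0, 0.01)  # tie-free
    res <- wilcoxon_rank_sum(x, y)
    # independent enumeration oracle
    pooled <- c(x, y)
    r <- rank(pooled)
    splits <- utils::combn(12, 6)
    W <- colSums(matrix(r[splits], nrow = 6))
    EW <- 6 * 13 / 2
    p_brute <- mean(abs(W - EW) >= abs(sum(r[1:6]) - EW) - 1e-8)
    expect_equal(res$p_value, p_brute)
    # and the reference implementation agrees on tie-free data
    expect_equal(res$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("exact p is invariant under common shifts and group swaps", {
  x <- c(3, 8, 1, 9, 4, 4)
  y <- c(7, 2, 10, 6, 6, 12)
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(wilcoxon_rank_sum(x + 100, y + 100)$p_value, p0)
  expect_equal(wilcoxon_rank_sum(y, x)$p_value, p0)
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(12)
  x <- rnorm(20)
  y <- rnorm(20, 1)
  res <- wilcoxon_rank_sum(x, y)
  expect_false(res$exact)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-10)
  # tied data against the reference too
  xt <- rep(1:5, 3)
  yt <- rep(2:6, 3)
  expect_equal(wilcoxon_rank_sum(xt, yt)$p_value,
               suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE,
                                                   correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("spearman_rho is the Pearson correlation of midranks", {
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_rho(1:5, rev(1:5)), -1)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  set.seed(9)
  x <- rnorm(20)
  y <- x + rnorm(20)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 2:3), "at least 3")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("post-hoc power reproduces the study's 0.318 and behaves at the null", {
  p <- posthoc_power(d = 0.8, n1 = 6, n2 = 6, alpha = 0.10)
  expect_lt(abs(p - 0.318), 0.02)
  # d = 0 returns exactly alpha for any method
  expect_equal(posthoc_power(0, 6, 6, alpha = 0.10), 0.10)
  expect_equal(posthoc_power(0, 6, 6, alpha = 0.05, method = "t_test"), 0.05)
  expect_error(posthoc_power(0.8, 1, 6), ">= 2")
  expect_error(posthoc_power(0.8, 6, 6, alpha = 1.2), "alpha")
  expect_error(posthoc_power(-1, 6, 6), "d")
})

test_that("power is monotone in effect size, sample size and alpha", {
  for (m in c("wmw_are", "t_test")) {
    by_d <- vapply(c(0.2, 0.5, 0.8, 1.2), posthoc_power, numeric(1),
                   n1 = 6, n2 = 6, alpha = 0.10, method = m)
    by_n <- vapply(c(4, 6, 12, 24), function(n) {
      posthoc_power(0.8, n, n, alpha = 0.10, method = m)
    }, numeric(1))
    by_a <- vapply(c(0.01, 0.05, 0.10, 0.20), function(a) {
      posthoc_power(0.8, 6, 6, alpha = a, method = m)
    }, numeric(1))
    expect_true(all(diff(by_d) > 0))
    expect_true(all(diff(by_n) > 0))
    expect_true(all(diff(by_a) > 0))
  }
})

test_that("analytic power agrees with a Monte-Carlo of the implemented test", {
  set.seed(314)
  B <- 1e4
  rej <- 0L
  for (i in seq_len(B)) {
    x <- rnorm(6)
    y <- rnorm(6, 0.8)
    if (wilcoxon_rank_sum(x, y)$p_value < 0.10) rej <- rej + 1L
  }
  expect_lt(abs(rej / B - posthoc_power(0.8, 6, 6, alpha = 0.10)), 0.015)
})

test_that("cohort comparison reports medians, tests and correlations", {
  sync <- tibble::tibble(total_switches = c(3, 5, 8, 2, 4),
                         unique_images = c(2, 3, 4, 2, 3))
  coun <- tibble::tibble(total_switches = c(40, 55, 38, 61, 45),
                         unique_images = c(12, 15, 11, 18, 13))
  rep_ <- compare_cohorts(sync, coun)
  expect_equal(rep_$medians$sync_median,
               c(median(sync$total_switches), median(sync$unique_images)))
  expect_equal(rep_$medians$counterbalance_median,
               c(median(coun$total_switches), median(coun$unique_images)))
  expect_equal(rep_$tests$p_value[1],
               wilcoxon_rank_sum(sync$total_switches,
                                 coun$total_switches)$p_value)
  expect_equal(diag(rep_$spearman), c(total_switches = 1, unique_images = 1))
  expect_error(compare_cohorts(sync[1, ], coun), "at least 2")
})

test_that("identical arms give p = 1 and reports round-trip through JSON", {
  arm <- tibble::tibble(total_switches = c(3, 5, 8), unique_images = c(2, 3, 4))
  rep_ <- compare_cohorts(arm, arm)
  expect_true(all(rep_$tests$p_value == 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, f)
  back <- read_report(f)
  expect_equal(back$medians, rep_$medians)
  expect_equal(back$tests, rep_$tests)
  expect_equal(back$spearman, rep_$spearman)
  expect_equal(back$alpha, rep_$alpha)
})

test_that("tidiers expose test and report results as tibbles", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tidy(res)$p.value, res$p_value)
  expect_equal(glance(res)$n1, 3)
  arm1 <- tibble::tibble(total_switches = c(3, 5, 8), unique_images = c(2, 3, 4))
  arm2 <- tibble::tibble(total_switches = c(9, 12, 20), unique_images = c(5, 6, 9))
  rep_ <- compare_cohorts(arm1, arm2)
  expect_equal(nrow(tidy(rep_)), 2)
  expect_true(all(c("index", "sync_median", "p_value") %in% names(tidy(rep_))))
  expect_equal(glance(rep_)$n_sync, 3)
})
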