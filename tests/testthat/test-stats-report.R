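test_that("uniformly signed n = 7 differences give T = 0 and p = 0.018", {
  pre <- c(3.1, 2.8, 4.0, 3.3, 3.6, 2.9, 3.8)
  post <- pre + c(10, 12, 9, 20, 4, 7, 18)
  res <- wilcoxon_paired(pre, post)
  expect_equal(res$w_statistic, 0)
  expect_equal(round(res$p_two_sided, 3), 0.018)
  expect_equal(res$z_value, -14 / sqrt(35), tolerance = 1e-12)
  # cross-check against the standard asymptotic test without correction
  ref <- stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-9)
})

test_that("asymptotic p agrees with wilcox.test on mixed-sign data", {
  set.seed(4)
  for (i in 1:5) {
    pre <- rnorm(9)
    post <- pre + rnorm(9, 0.3)
    res <- wilcoxon_paired(pre, post)
    ref <- stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE,
                              correct = FALSE)
    expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-9)
  }
})

test_that("exact enumeration matches a brute-force oracle", {
  pre <- c(1, 2, 3, 4, 5, 6, 7)
  post <- pre + c(0.5, 1.1, -0.2, 2.3, 0.9, 1.7, 0.4)
  res <- wilcoxon_paired(pre, post, method = "exact")
  # oracle: all 2^7 sign assignments of the ranked absolute differences
  r <- rank(abs(post - pre))
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 7)))
  wplus <- apply(grid, 1, function(s) sum(r[s]))
  p_oracle <- min(1, 2 * mean(wplus <= res$w_statistic))
  expect_equal(res$p_two_sided, p_oracle, tolerance = 1e-12)
  # monotone case: exact p is 2/2^7, below the asymptotic 0.018
  ex <- wilcoxon_paired(pre, pre + 1:7, method = "exact")
  expect_equal(ex$p_two_sided, 2 / 2^7, tolerance = 1e-12)
  asym <- wilcoxon_paired(pre, pre + 1:7)
  expect_gt(asym$p_two_sided, ex$p_two_sided)
})

test_that("signed-rank conventions: swap symmetry, zero drops, errors", {
  pre <- c(10, 12, 9, 20, 4, 7, 18)
  post <- c(11, 10, 9, 25, 8, 6, 18)    # two zeros dropped
  a <- wilcoxon_paired(pre, post)
  b <- wilcoxon_paired(post, pre)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
  expect_equal(a$n_used, 5)
  expect_error(wilcoxon_paired(pre, pre), "all paired differences are zero")
  expect_error(wilcoxon_paired(1:4, 2:5), "n >= 5")
  expect_error(wilcoxon_paired(1:6, 1:5), "equal length")
})

test_that("the asymptotic test holds its nominal size at n = 7", {
  set.seed(1234)
  reps <- 2000
  hits <- 0
  for (i in seq_len(reps)) {
    d <- rnorm(7)
    if (wilcoxon_paired(rep(0, 7), d)$p_two_sided < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("Pearson p-values reproduce the one-sided t-tail convention", {
  expect_equal(round(pearson_p(0.707, 7)$p_one_sided, 3), 0.038)
  expect_equal(round(pearson_p(0.724, 7)$p_one_sided, 3), 0.033)
  pr <- pearson_p(0.55, 9)
  expect_equal(pr$p_two_sided, 2 * pr$p_one_sided, tolerance = 1e-12)
})

test_that("pearson_correlation matches cor.test on real vectors", {
  # construct vectors with an exact target correlation
  target <- 0.707
  x <- scale(1:7)[, 1]
  set.seed(9)
  z <- rnorm(7)
  z <- scale(stats::resid(stats::lm(z ~ x)))[, 1]
  y <- target * x + sqrt(1 - target^2) * z
  res <- pearson_correlation(x, y, "x", "y")
  expect_equal(res$r, target, tolerance = 1e-9)
  expect_equal(round(res$p_one_sided, 3), 0.038)
  ref <- stats::cor.test(x, y, alternative = "greater")
  expect_equal(res$p_one_sided, ref$p.value, tolerance = 1e-9)
  ref2 <- stats::cor.test(x, y)
  expect_equal(res$p_two_sided, ref2$p.value, tolerance = 1e-9)
})

test_that("degenerate correlations are floored and flagged, not errors", {
  x <- as.numeric(1:6)
  res <- pearson_correlation(x, 2 * x)
  expect_true(res$degenerate)
  expect_equal(res$p_one_sided, 0)
  expect_error(pearson_correlation(x, rep(1, 6)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("negative correlations use the matching one-sided tail", {
  x <- as.numeric(1:8)
  set.seed(2)
  y <- -x + rnorm(8, 0, 2)
  res <- pearson_correlation(x, y)
  ref <- stats::cor.test(x, y, alternative = "less")
  expect_equal(res$p_one_sided, ref$p.value, tolerance = 1e-9)
})

test_that("build_report produces paired rows with SE = SD/sqrt(n)", {
  set.seed(5)
  n <- 7
  subj <- sprintf("g%d", 1:n)
  base_beta <- c(3.1, 3.4, 3.0, 3.9, 3.3, 3.6, 4.2)
  post_beta <- base_beta + c(5, 20, 9, 14, 3, 11, 25)
  metrics <- rbind(
    data.frame(subject_id = subj, condition = "baseline",
               beta = base_beta, hr_bpm = rnorm(n, 120, 5)),
    data.frame(subject_id = subj, condition = "after_evar",
               beta = post_beta, hr_bpm = rnorm(n, 120, 5)))
  rep <- build_report(metrics)
  beta_row <- rep$paired[rep$paired$metric == "beta", ]
  expect_equal(round(beta_row$p_two_sided, 3), 0.018)
  expect_equal(beta_row$mean_pre, mean(base_beta))
  expect_equal(beta_row$se_pre, sd(base_beta) / sqrt(n), tolerance = 1e-12)
  # hand-checked SE on a 3-value fixture: sd(1,2,3) = 1
  expect_equal(sd(c(1, 2, 3)) / sqrt(3), 1 / sqrt(3), tolerance = 1e-12)
})

test_that("build_report validates pairing and size", {
  m <- data.frame(subject_id = c("a", "a", "b"),
                  condition = c("baseline", "after_evar", "baseline"),
                  v = c(1, 2, 3))
  expect_error(build_report(m), "pairing error.*b")
  single <- data.frame(subject_id = "a",
                       condition = c("baseline", "after_evar"),
                       v = c(1, 2))
  expect_error(build_report(rbind(single)), "pairing error")
})

test_that("build_report correlation table reproduces the r and p conventions", {
  n <- 7
  subj <- sprintf("g%d", 1:n)
  x <- scale(1:n)[, 1]
  set.seed(10)
  z <- scale(stats::resid(stats::lm(rnorm(n) ~ x)))[, 1]
  y <- 0.707 * x + sqrt(1 - 0.707^2) * z
  metrics <- rbind(
    data.frame(subject_id = subj, condition = "baseline", dmax = x, nw = y),
    data.frame(subject_id = subj, condition = "after_evar", dmax = x, nw = y))
  rep <- build_report(metrics, correlations = "dmax", correlate_with = "nw")
  expect_equal(rep$correlations$r, 0.707, tolerance = 1e-9)
  expect_equal(round(rep$correlations$p_one_sided, 3), 0.038)
})
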