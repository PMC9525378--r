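# RCBD statistics: LS means, SEM, F-test, classification, letters, and
# the binomial grade-class model.

test_that("2x2 fit matches the hand-worked two-way ANOVA", {
  d <- data.frame(treatment = c("t1", "t1", "t2", "t2"),
                  block = c("b1", "b2", "b1", "b2"),
                  y = c(10, 12, 14, 18))
  # by hand: treatment means 11/16, block means 12/15, SSE = 1 on 1 df,
  # SS_trt = 25 -> F = 25, SEM = sqrt(MSE/2)
  fit <- fit_rcbd(d, "y")
  expect_equal(unname(fit$ls_means), c(11, 16))
  expect_equal(fit$sem, sqrt(1 / 2))
  expect_equal(fit$p_value, 1 - pf(25, 1, 1))
})

test_that("balanced LS means equal raw treatment means; constants shift", {
  set.seed(31)
  d <- rcbd_table(c(A = 0, B = 1, C = 2))
  fit <- fit_rcbd(d, "y")
  raw <- tapply(d$y, d$treatment, mean)
  expect_equal(unname(fit$ls_means),
               as.numeric(raw[names(fit$ls_means)]))
  d2 <- transform(d, y = y + 100)
  fit2 <- fit_rcbd(d2, "y")
  expect_equal(fit2$ls_means, fit$ls_means + 100)
  expect_equal(fit2$sem, fit$sem)
  expect_equal(fit2$p_value, fit$p_value)
})

test_that("fixed- and random-block treatment F agree when balanced", {
  set.seed(32)
  d <- rcbd_table(c(A = 0, B = 0.5, C = 1), block_sd = 2)
  f_fixed <- fit_rcbd(d, "y", block_effect = "fixed")
  f_rand <- fit_rcbd(d, "y", block_effect = "random")
  expect_equal(f_fixed$p_value, f_rand$p_value, tolerance = 1e-6)
  expect_equal(f_fixed$ls_means, f_rand$ls_means, tolerance = 1e-8)
})

test_that("unbalanced LS means agree with emmeans", {
  skip_if_not_installed("emmeans")
  set.seed(33)
  d <- rcbd_table(c(A = 0, B = 0.8, C = 0.4))[-c(3, 17), ]  # drop 2 pens
  fit <- fit_rcbd(d, "y")
  lmfit <- lm(y ~ treatment + block, data = d)
  em <- summary(emmeans::emmeans(lmfit, "treatment"))
  expect_equal(unname(fit$ls_means[em$treatment]), em$emmean,
               tolerance = 1e-10)
  expect_equal(unname(fit$se[em$treatment]), em$SE, tolerance = 1e-10)
})

test_that("zero-variance degenerate data take the p = 1 convention", {
  d <- expand.grid(treatment = c("A", "B", "C"),
                   block = c("b1", "b2"), stringsAsFactors = FALSE)
  d$y <- 5
  fit <- suppressWarnings(fit_rcbd(d, "y"))  # lm warns on a perfect fit
  expect_equal(unname(fit$ls_means), rep(5, 3))
  expect_equal(fit$p_value, 1)
  expect_equal(fit$classification, "ns")
})

test_that("design errors are caught", {
  d <- data.frame(treatment = "A", block = c("b1", "b2"), y = 1:2)
  expect_error(fit_rcbd(d, "y"), "2 treatments")
  d2 <- data.frame(treatment = c("A", "B"), block = "b1", y = 1:2)
  expect_error(fit_rcbd(d2, "y"), "2 blocks")
})

test_that("significance classification uses the 0.05/0.10 thresholds", {
  expect_equal(classify_significance(c(0.04, 0.05, 0.08, 0.10, 0.29, NA)),
               c("significant", "significant", "tendency", "tendency",
                 "ns", "ns"))
})

test_that("type-I error of the F-test is calibrated at the 5% level", {
  set.seed(2026)
  n_rep <- 2000
  rejected <- 0L
  for (i in seq_len(n_rep)) {
    d <- rcbd_table(c(A = 0, B = 0, C = 0), block_sd = 1, resid_sd = 0.5)
    p <- fit_rcbd(d, "y", pairwise = FALSE)$p_value
    rejected <- rejected + (p <= 0.05)
  }
  rate <- rejected / n_rep
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - ci_half)
  expect_lt(rate, 0.05 + ci_half)
})

test_that("letter grouping reproduces the high/intermediate/low pattern", {
  # top and bottom differ, middle shares with both: a / ab / b
  lg <- letter_grouping(
    c(CON = 2.78, CBCDS = 2.66, WCGF = 2.61),
    data.frame(a = c("CON", "CON", "CBCDS"),
               b = c("CBCDS", "WCGF", "WCGF"),
               p_value = c(0.15, 0.04, 0.45)), alpha = 0.10)
  expect_equal(lg, c(CON = "a", CBCDS = "ab", WCGF = "b"))
  # no pair differs: everyone shares one letter
  lg2 <- letter_grouping(c(A = 1, B = 2, C = 3),
                         data.frame(a = c("A", "A", "B"),
                                    b = c("B", "C", "C"),
                                    p_value = rep(0.9, 3)))
  expect_equal(unname(lg2), rep("a", 3))
  # all pairs differ: three distinct letters
  lg3 <- letter_grouping(c(A = 3, B = 2, C = 1),
                         data.frame(a = c("A", "A", "B"),
                                    b = c("B", "C", "C"),
                                    p_value = rep(0.01, 3)))
  expect_equal(lg3, c(A = "a", B = "b", C = "c"))
})

test_that("binomial fit matches the closed-form contingency oracle", {
  # blocks identical, so the fit collapses to pooled per-treatment
  # proportions; the treatment LRT equals the hand-computed deviance
  d <- data.frame(treatment = rep(c("t1", "t2"), each = 2),
                  block = rep(c("b1", "b2"), 2),
                  s = c(3, 3, 5, 5), n = 8)
  fit <- fit_binomial_proportions(d, "s", "n")
  expect_equal(unname(fit$ls_means), c(100 * 3 / 8, 100 * 5 / 8),
               tolerance = 1e-6)
  # hand LRT: null proportion pooled at 0.5 everywhere
  p1 <- 3 / 8; p2 <- 5 / 8; p0 <- 0.5
  ll <- function(s, n, p) s * log(p) + (n - s) * log(1 - p)
  stat <- 2 * (ll(6, 16, p1) + ll(10, 16, p2) - ll(6, 16, p0) -
                 ll(10, 16, p0))
  expect_equal(fit$p_value, 1 - pchisq(stat, df = 1), tolerance = 1e-6)
  expect_false(fit$separation)
})

test_that("equal counts give equal fitted proportions", {
  d <- data.frame(treatment = rep(c("t1", "t2", "t3"), each = 2),
                  block = rep(c("b1", "b2"), 3), s = 4, n = 8)
  fit <- fit_binomial_proportions(d, "s", "n")
  expect_equal(unname(fit$ls_means), rep(50, 3), tolerance = 1e-8)
})

test_that("an empty category is flagged as separation at the boundary", {
  d <- data.frame(treatment = rep(c("t1", "t2"), each = 2),
                  block = rep(c("b1", "b2"), 2), s = c(0, 0, 4, 4), n = 8)
  fit <- fit_binomial_proportions(d, "s", "n")
  expect_true(fit$separation)
  expect_lt(fit$ls_means[["t1"]], 1)
})
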