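test_that("binomial criterion agrees with exhaustive tail enumeration", {
  # brute force: for each k, sum the exact binomial pmf over k..n
  brute <- function(n, alpha, p0 = 0.5) {
    for (k in 0:n) {
      tail <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
      if (tail < alpha) return(k)
    }
    NA_integer_
  }
  for (n in c(10, 20, 47, 110, 200)) {
    for (alpha in c(0.05, 0.01, 0.001)) {
      bc <- binomial_criterion(n, alpha)
      expect_equal(bc$k, brute(n, alpha), info = sprintf("n=%d a=%g", n, alpha))
    }
  }
  # pooled design of ~110 trials per grating: P < 0.01 gives 68/110 = 61.8%
  bc <- binomial_criterion(110, 0.01)
  expect_equal(bc$k, 68)
  expect_equal(bc$proportion, 68 / 110)
  expect_equal(bc$percent, 62)
  # a single trial can never beat chance at alpha = 0.01
  expect_false(binomial_criterion(1, 0.01)$attainable)
})

test_that("ML fit recovers a planted logistic observer", {
  sim <- make_trials(3.0, slope = 2, n_per_frequency = 4000, seed = 77)
  fit <- fit_psychometric(x = sim$trials$spatial_frequency_cpd,
                          correct = sim$trials$correct)
  truth <- sim$ledger$truth
  # with 4000 trials per level the curve parameters are tightly identified
  expect_equal(unname(coef(fit)["alpha"]), truth$alpha, tolerance = 0.02)
  expect_equal(unname(coef(fit)["beta"]), truth$slope, tolerance = 0.05)
  thr <- interpolate_threshold(fit)$threshold
  expect_equal(thr, truth$true_threshold_cpd, tolerance = 0.02)
})

test_that("formula and vector interfaces agree", {
  sim <- make_trials(2.5, seed = 3)
  f1 <- fit_psychometric(correct ~ spatial_frequency_cpd, sim$trials)
  f2 <- fit_psychometric(x = sim$trials$spatial_frequency_cpd,
                         correct = sim$trials$correct)
  expect_equal(coef(f1), coef(f2))
  expect_equal(logLik(f1), logLik(f2))
})

test_that("degenerate and reversed data are flagged, not hidden", {
  x <- rep(c(1, 2, 3), each = 20)
  expect_warning(fit_all <- fit_psychometric(x = x, correct = rep(1, 60)),
                 "identical")
  expect_true(fit_all$separation)
  set.seed(1)
  rising <- rbinom(60, 1, rep(c(0.55, 0.7, 0.95), each = 20))
  expect_warning(fit_rev <- fit_psychometric(x = x, correct = rising),
                 "rises")
  expect_true(fit_rev$reversed)
})

test_that("a two-level fit is saturated with zero deviance", {
  x <- rep(c(1, 3), each = 50)
  set.seed(8)
  correct <- c(rbinom(50, 1, 0.95), rbinom(50, 1, 0.60))
  fit <- fit_psychometric(x = x, correct = correct)
  expect_equal(fit$deviance, 0, tolerance = 1e-5)
})

test_that("threshold interpolation inverts the fitted curve", {
  sim <- make_trials(3.94, seed = 5)
  fit <- fit_psychometric(x = sim$trials$spatial_frequency_cpd,
                          correct = sim$trials$correct)
  # midpoint property: at criterion 0.75 the threshold is alpha
  expect_equal(interpolate_threshold(fit, 0.75)$threshold,
               unname(coef(fit)["alpha"]), tolerance = 1e-10)
  # inversion identity at the default criterion
  thr <- interpolate_threshold(fit, 0.62)$threshold
  expect_equal(unname(predict(fit, thr)), 0.62, tolerance = 1e-10)
  expect_error(interpolate_threshold(fit, 0.4), "criterion")
  expect_error(interpolate_threshold(fit, 1.0), "criterion")
})

test_that("threshold estimation is equivariant under frequency rescaling", {
  sim <- make_trials(2.2, seed = 13)
  x <- sim$trials$spatial_frequency_cpd
  fit1 <- fit_psychometric(x = x, correct = sim$trials$correct)
  fit2 <- fit_psychometric(x = 3 * x, correct = sim$trials$correct)
  expect_equal(interpolate_threshold(fit2)$threshold,
               3 * interpolate_threshold(fit1)$threshold,
               tolerance = 1e-4)
})

test_that("deviance on well-specified data sits in the expected range", {
  devs <- vapply(1:40, function(i) {
    sim <- make_trials(3.94, seed = 400 + i)
    fit <- fit_psychometric(x = sim$trials$spatial_frequency_cpd,
                            correct = sim$trials$correct)
    fit$deviance
  }, numeric(1))
  # 10 levels - 2 parameters: deviance ~ chi-squared(8); a conventional
  # acceptance bound near 8.6 captures most well-specified fits
  expect_gt(mean(devs < 8.6), 0.3)
  expect_lt(median(devs), qchisq(0.9, df = 8))
})

test_that("bootstrap CIs are deterministic given a seed and shrink with n", {
  sim <- make_trials(3.0, seed = 9)
  fit <- fit_psychometric(x = sim$trials$spatial_frequency_cpd,
                          correct = sim$trials$correct)
  ci1 <- bootstrap_ci(fit, n_boot = 99, seed = 42)
  ci2 <- bootstrap_ci(fit, n_boot = 99, seed = 42)
  expect_identical(c(ci1$ci_low, ci1$ci_high), c(ci2$ci_low, ci2$ci_high))
  expect_true(ci1$ci_low <= ci1$threshold && ci1$threshold <= ci1$ci_high)
  # near-zero noise: huge per-level n makes the interval collapse
  big <- make_trials(3.0, slope = 2, n_per_frequency = 20000, seed = 10)
  fit_big <- fit_psychometric(x = big$trials$spatial_frequency_cpd,
                              correct = big$trials$correct)
  ci_big <- bootstrap_ci(fit_big, n_boot = 99, seed = 42)
  expect_lt(ci_big$ci_high - ci_big$ci_low,
            (ci1$ci_high - ci1$ci_low) / 3)
})

test_that("median threshold recovery error is under 10% across observers", {
  errs <- vapply(1:60, function(i) {
    thr_true <- runif(1, 1.5, 4.2)
    sim <- make_trials(thr_true, slope = 2, n_per_frequency = 110,
                       seed = 6000 + i)
    fit <- fit_psychometric(x = sim$trials$spatial_frequency_cpd,
                            correct = sim$trials$correct)
    abs(interpolate_threshold(fit)$threshold -
          sim$ledger$truth$true_threshold_cpd) /
      sim$ledger$truth$true_threshold_cpd
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("treatment comparison: identical sets give p near 1, disjoint the minimum", {
  thr <- data.frame(
    fish_id = rep(paste0("f", 1:4), 2),
    treatment = rep(c("achromatic", "green_yellow"), each = 4),
    threshold = c(3.8, 4.0, 3.9, 3.7, 3.8, 4.0, 3.9, 3.7))
  res <- compare_treatments(thr, n_perm = 499, seed = 1)
  expect_gt(res$p_value, 0.9)
  expect_true(res$paired)
  # non-overlapping unpaired sets: exhaustive enumeration over C(4,2) = 6
  # label assignments gives a minimal two-sided p of 2/6 under exchange
  thr2 <- data.frame(fish_id = paste0("g", 1:4),
                     treatment = rep(c("a", "b"), each = 2),
                     threshold = c(3.8, 4.0, 1.6, 1.8))
  res2 <- compare_treatments(thr2, n_perm = 1999, seed = 2)
  expect_false(res2$paired)
  expect_lt(res2$p_value, 0.45)
  expect_gt(res2$p_value, 0.25)
  expect_error(compare_treatments(thr[thr$treatment == "achromatic", ]),
               "two treatments")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(99)
  ps <- vapply(1:60, function(i) {
    thr <- data.frame(fish_id = paste0("f", 1:8),
                      treatment = rep(c("a", "b"), each = 4),
                      threshold = rnorm(8, 3, 0.5))
    compare_treatments(thr, n_perm = 199)$p_value
  }, numeric(1))
  # uniform-ish: roughly 10% below 0.1, none concentrated at 0
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.1), 0.3)
})

test_that("model methods behave like standard fitted-model accessors", {
  sim <- make_trials(3.0, seed = 17)
  fit <- fit_psychometric(correct ~ spatial_frequency_cpd, sim$trials)
  expect_named(coef(fit), c("alpha", "beta"))
  expect_s3_class(fit, "psychfit")
  expect_equal(attr(logLik(fit), "df"), 2)
  expect_equal(length(residuals(fit)), nrow(fit$data))
  # deviance residuals reproduce the total deviance
  expect_equal(sum(residuals(fit)^2), deviance(fit), tolerance = 1e-8)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(length(sims), 3)
  expect_true(all(sims[[1]]$k <= sims[[1]]$n))
  # plot runs silently to a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit, ci = c(2.5, 3.5)))
})
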