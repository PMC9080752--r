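# Psychometric functions for two-alternative grating discrimination.
#
# The probability of choosing the rewarded grating at spatial frequency x is
# modelled as psi(x) = gamma + (1 - gamma - lambda) / (1 + exp(beta*(x - alpha)))
# with guess rate gamma fixed at 0.5 (two-passage forced choice) and lapse
# rate lambda fixed at 0: performance starts near 1 for coarse gratings and
# falls to chance as the grating becomes too fine to resolve. (alpha, beta)
# are estimated by Bernoulli maximum likelihood. The acuity threshold is the
# frequency where psi crosses the binomial significance criterion (62% for
# 110 pooled trials per grating at P < 0.01).

#' Minimal proportion significantly above chance (exact binomial)
#'
#' Smallest `k/n` such that the one-tailed exact binomial tail
#' `P(X >= k | n, p0)` is below `alpha`.
#'
#' @param n_trials Pooled number of trials per stimulus level.
#' @param alpha Significance level (default 0.01).
#' @param p0 Chance probability (default 0.5).
#' @return List with `k`, `proportion`, `percent` (rounded to integer
#'   percent) and `attainable`. When even `k = n` is not significant,
#'   `attainable` is `FALSE` and the other entries are `NA`.
#' @export
binomial_criterion <- function(n_trials, alpha = 0.01, p0 = 0.5) {
  stopifnot(n_trials >= 1, alpha > 0, alpha < 1, p0 > 0, p0 < 1)
  # P(X >= k) for k = 0..n
  tail_p <- c(1, pbinom(0:(n_trials - 1), n_trials, p0,
                        lower.tail = FALSE))
  ok <- which(tail_p < alpha)
  if (!length(ok))
    return(list(k = NA_integer_, proportion = NA_real_, percent = NA_real_,
                attainable = FALSE))
  k <- ok[1] - 1L
  list(k = k, proportion = k / n_trials,
       percent = round(100 * k / n_trials), attainable = TRUE)
}

psi_fun <- function(x, alpha, beta, guess = 0.5, lapse = 0) {
  guess + (1 - guess - lapse) * plogis(-beta * (x - alpha))
}

aggregate_trials <- function(x, correct) {
  agg <- aggregate(list(k = correct), by = list(x = x), FUN = sum)
  agg$n <- as.vector(table(factor(x, levels = sort(unique(x)))))
  agg[order(agg$x), ]
}

nll_psych <- function(par, agg, guess, lapse) {
  p <- psi_fun(agg$x, par[1], exp(par[2]), guess, lapse)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
}

#' Fit a logistic psychometric function
#'
#' Maximum-likelihood fit of the two-parameter logistic (location `alpha`,
#' slope `beta`) with fixed guess and lapse rates to Bernoulli choice data.
#' Data may be given as a formula `correct ~ spatial_frequency` with a data
#' frame, or as bare vectors.
#'
#' @param formula Model formula, response a 0/1 correct indicator and a
#'   single stimulus-level covariate (spatial frequency, cpd).
#' @param data Data frame holding the formula variables.
#' @param x,correct Alternative direct interface: stimulus levels and 0/1
#'   outcomes.
#' @param guess Guess rate, fixed (default 0.5).
#' @param lapse Lapse rate, fixed (default 0).
#' @param max_slope Cap on `beta`; fits hitting the cap (complete
#'   separation) are flagged. Default 50 per cpd.
#' @return Object of class `psychfit` with coefficients `alpha` (location)
#'   and `beta` (slope), log-likelihood, deviance against the saturated
#'   model, per-level aggregated data and flags `separation` (slope at cap)
#'   and `reversed` (performance rising with frequency).
#' @export
fit_psychometric <- function(formula = NULL, data = NULL, x = NULL,
                             correct = NULL, guess = 0.5, lapse = 0,
                             max_slope = 50) {
  if (!is.null(formula)) {
    mf <- model.frame(formula, data)
    correct <- mf[[1]]
    x <- mf[[2]]
  }
  if (is.null(x) || is.null(correct))
    stop("supply either a formula with data, or 'x' and 'correct'")
  if (!all(correct %in% c(0, 1))) stop("'correct' must be 0/1")
  if (any(x <= 0)) stop("spatial frequencies must be positive")
  agg <- aggregate_trials(x, correct)
  out <- fit_psych_agg(agg, guess, lapse, max_slope)
  out$call <- match.call()
  out
}

# core ML fit on per-level aggregated counts (x, k, n)
fit_psych_agg <- function(agg, guess = 0.5, lapse = 0, max_slope = 50) {
  if (nrow(agg) < 2) stop("at least 2 distinct stimulus levels are required")
  degenerate <- all(agg$k == agg$n) || all(agg$k == 0)
  if (degenerate)
    warning("all outcomes identical; fit is degenerate")
  # start: location near mid-range, moderate slope
  start <- c(alpha = mean(range(agg$x)), logbeta = log(2))
  opt <- optim(start, nll_psych, agg = agg, guess = guess, lapse = lapse,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  alpha <- unname(opt$par[1])
  beta <- exp(unname(opt$par[2]))
  separation <- degenerate
  if (beta > max_slope) {
    beta <- max_slope
    # re-profile alpha at the capped slope
    prof <- optimize(function(a) nll_psych(c(a, log(max_slope)), agg,
                                           guess, lapse),
                     range(agg$x) + c(-1, 1))
    alpha <- prof$minimum
    separation <- TRUE
  }
  ll <- -nll_psych(c(alpha, log(beta)), agg, guess, lapse)
  phat <- pmin(pmax(agg$k / agg$n, 1e-12), 1 - 1e-12)
  ll_sat <- sum(agg$k * log(phat) + (agg$n - agg$k) * log(1 - phat))
  dev <- 2 * (ll_sat - ll)
  slope_cor <- suppressWarnings(stats::cor(agg$x, agg$k / agg$n))
  reversed <- isTRUE(slope_cor > 0 && nrow(agg) > 2)
  if (reversed)
    warning("performance rises with spatial frequency; check the data")
  structure(list(
    coefficients = c(alpha = alpha, beta = beta),
    guess = guess, lapse = lapse,
    logLik = ll, deviance = dev, df = nrow(agg) - 2,
    data = agg, n_trials = sum(agg$n),
    separation = separation, reversed = reversed,
    call = NULL
  ), class = "psychfit")
}

#' @exportS3Method stats::coef
coef.psychfit <- function(object, ...) object$coefficients

#' @exportS3Method stats::logLik
logLik.psychfit <- function(object, ...) {
  structure(object$logLik, df = 2, class = "logLik")
}

#' @export
deviance.psychfit <- function(object, ...) object$deviance

#' @export
print.psychfit <- function(x, ...) {
  cat("Logistic psychometric fit (Bernoulli ML)\n")
  cat(sprintf("  guess rate %.2f, lapse rate %.2f (fixed)\n",
              x$guess, x$lapse))
  cat(sprintf("  location alpha = %.3f cpd, slope beta = %.3f per cpd\n",
              x$coefficients["alpha"], x$coefficients["beta"]))
  cat(sprintf("  logLik %.2f, deviance %.2f on %d df, %d trials\n",
              x$logLik, x$deviance, x$df, x$n_trials))
  if (x$separation) cat("  note: slope capped (complete separation)\n")
  if (x$reversed) cat("  warning: performance rises with frequency\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.psychfit <- function(object, criterion = 0.62, ...) {
  thr <- interpolate_threshold(object, criterion)
  out <- list(fit = object, criterion = criterion, threshold = thr$threshold)
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %.0f%% threshold: %.3f cpd\n", 100 * x$criterion,
              x$threshold))
  invisible(x)
}

#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata[[1]] else newdata
  psi_fun(x, object$coefficients["alpha"], object$coefficients["beta"],
          object$guess, object$lapse)
}

#' @exportS3Method stats::residuals
residuals.psychfit <- function(object, type = c("deviance", "pearson"),
                               ...) {
  type <- match.arg(type)
  agg <- object$data
  p <- predict(object)
  phat <- agg$k / agg$n
  if (type == "pearson")
    return((agg$k - agg$n * p) / sqrt(agg$n * p * (1 - p)))
  sgn <- sign(phat - p)
  ph <- pmin(pmax(phat, 1e-12), 1 - 1e-12)
  dev_i <- 2 * (agg$k * log(ph / p) +
                  (agg$n - agg$k) * log((1 - ph) / (1 - p)))
  sgn * sqrt(pmax(dev_i, 0))
}

#' Simulate choice data from a fitted psychometric function
#'
#' Parametric resampling: binomial redraws at each observed frequency from
#' the fitted psi.
#'
#' @param object A `psychfit`.
#' @param nsim Number of simulated data sets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of data frames with columns `x`, `k`, `n`.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  agg <- object$data
  lapply(seq_len(nsim), function(i)
    data.frame(x = agg$x, k = rbinom(nrow(agg), agg$n, p), n = agg$n))
}

#' @exportS3Method base::plot
plot.psychfit <- function(x, criterion = 0.62, ci = NULL, ...) {
  agg <- x$data
  xx <- seq(min(agg$x), max(agg$x), length.out = 200)
  plot(agg$x, agg$k / agg$n, ylim = c(0.3, 1), pch = 16,
       xlab = "spatial frequency (cpd)", ylab = "proportion correct", ...)
  lines(xx, psi_fun(xx, x$coefficients["alpha"], x$coefficients["beta"],
                    x$guess, x$lapse))
  abline(h = x$guess, lty = 3)
  thr <- interpolate_threshold(x, criterion)$threshold
  abline(v = thr, lty = 2)
  if (!is.null(ci)) {
    arrows(ci[1], criterion, ci[2], criterion, angle = 90, code = 3,
           length = 0.04)
  }
  invisible(x)
}

#' Interpolate the acuity threshold of a psychometric fit
#'
#' Closed-form inversion of psi at the criterion probability:
#' `threshold = alpha - qlogis((c - guess) / (1 - guess - lapse)) / beta`.
#'
#' @param fit A `psychfit`.
#' @param criterion Criterion probability, strictly between the guess rate
#'   and `1 - lapse` (default 0.62, the binomial criterion for 110 pooled
#'   trials at P < 0.01).
#' @return List with `threshold` (cpd) and `criterion`.
#' @export
interpolate_threshold <- function(fit, criterion = 0.62) {
  g <- fit$guess; l <- fit$lapse
  if (criterion <= g || criterion >= 1 - l)
    stop(sprintf("criterion must lie strictly between %g and %g", g, 1 - l))
  a <- fit$coefficients["alpha"]; b <- fit$coefficients["beta"]
  thr <- unname(a - qlogis((criterion - g) / (1 - g - l)) / b)
  list(threshold = thr, criterion = criterion)
}

#' Parametric bootstrap confidence interval for the threshold
#'
#' Binomial redraws at each frequency from the fitted psi, refit, and the
#' percentile interval of the resampled thresholds.
#'
#' @param fit A `psychfit`.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed; a fixed seed gives a bit-identical interval.
#' @param criterion Criterion probability (default 0.62).
#' @param level Confidence level (default 0.95).
#' @return Object of class `threshold_estimate`: `threshold`, `criterion`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_failed`.
#' @export
bootstrap_ci <- function(fit, n_boot = 2000, seed = NULL, criterion = 0.62,
                         level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  agg <- fit$data
  p <- predict(fit)
  thr0 <- interpolate_threshold(fit, criterion)$threshold
  thrs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    bagg <- data.frame(x = agg$x, k = rbinom(nrow(agg), agg$n, p),
                       n = agg$n)
    fb <- try(suppressWarnings(
      fit_psych_agg(bagg, guess = fit$guess, lapse = fit$lapse)),
      silent = TRUE)
    if (!inherits(fb, "try-error"))
      thrs[b] <- interpolate_threshold(fb, criterion)$threshold
  }
  failed <- sum(is.na(thrs))
  if (failed > 0.1 * n_boot)
    stop(sprintf("%d of %d bootstrap refits failed", failed, n_boot))
  qs <- quantile(thrs, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  structure(list(threshold = thr0, criterion = criterion,
                 ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, n_failed = failed, level = level),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("%.0f%% threshold: %.2f cpd (%.0f%% CI: %.2f-%.2f)\n",
              100 * x$criterion, x$threshold, 100 * x$level,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Permutation test for treatment differences in acuity thresholds
#'
#' Pairwise comparison of mean per-fish thresholds between treatments. When
#' every fish contributing to a pair was tested under both treatments, the
#' labels are permuted within fish (a paired sign-flip test); otherwise
#' treatment labels are permuted across fish. The p-value is
#' `(1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)` for the difference in
#' means.
#'
#' @param thresholds Data frame with columns `fish_id`, `treatment`,
#'   `threshold`.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @return Data frame of pairwise comparisons: `treatment_a`, `treatment_b`,
#'   `diff_means`, `p_value`, `paired`.
#' @export
compare_treatments <- function(thresholds, n_perm = 2000, seed = NULL) {
  needed <- c("fish_id", "treatment", "threshold")
  if (!all(needed %in% names(thresholds)))
    stop("'thresholds' needs columns: ", paste(needed, collapse = ", "))
  trt <- unique(thresholds$treatment)
  if (length(trt) < 2) stop("at least two treatments are required")
  if (!is.null(seed)) set.seed(seed)
  pairs <- utils::combn(trt, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    d <- thresholds[thresholds$treatment %in% pr, , drop = FALSE]
    tab <- table(d$fish_id, d$treatment)
    if (any(table(d$treatment) < 2))
      stop("at least 2 fish per treatment are required")
    paired <- all(rowSums(tab > 0) == 2)
    obs <- mean(d$threshold[d$treatment == pr[1]]) -
      mean(d$threshold[d$treatment == pr[2]])
    stat <- numeric(n_perm)
    if (paired) {
      wide <- merge(d[d$treatment == pr[1], c("fish_id", "threshold")],
                    d[d$treatment == pr[2], c("fish_id", "threshold")],
                    by = "fish_id")
      diffs <- wide$threshold.x - wide$threshold.y
      for (i in seq_len(n_perm))
        stat[i] <- mean(diffs * sample(c(-1, 1), length(diffs),
                                       replace = TRUE))
      obs <- mean(diffs)
    } else {
      for (i in seq_len(n_perm)) {
        lab <- sample(d$treatment)
        stat[i] <- mean(d$threshold[lab == pr[1]]) -
          mean(d$threshold[lab == pr[2]])
      }
    }
    data.frame(treatment_a = pr[1], treatment_b = pr[2], diff_means = obs,
               p_value = (1 + sum(abs(stat) >= abs(obs) - 1e-12)) /
                 (n_perm + 1),
               paired = paired)
  }))
  rownames(out) <- NULL
  out
}
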