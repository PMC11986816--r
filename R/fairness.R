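# Fairness and accuracy statistics --------------------------------------------
#
# The evaluation protocol: per-group confusion-matrix rates, the equal
# opportunity difference (EOD = TPR gap between race groups), a one-sample
# t-test on the EOD series across folds or bootstrap replicates, Hedges'
# g_rm and the common-language effect size for the paired TPR series,
# McNemar's test against rule-based comparators, DeLong's test for
# correlated AUCs, stratified bootstrap confidence intervals, and a
# Monte-Carlo (Lilliefors-style) Kolmogorov-Smirnov normality check.

comparison_result <- function(test, statistic, p, n, ...) {
  structure(c(list(test = test, statistic = statistic, p = p, n = n),
              list(...)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.5g, p = %.4g (n = %s)%s\n", x$test,
              x$statistic, x$p, paste(x$n, collapse = "/"),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Per-group confusion-matrix rates
#'
#' @param eligible 0/1 predicted eligibility.
#' @param labels 0/1 outcome labels.
#' @param group grouping vector (e.g. race).
#' @return A data.frame of class `group_rates`, one row per group level:
#'   counts (tp, fn, fp, tn) and rates (tpr, fnr, fpr, specificity). A group
#'   with no positive labels has `NA` TPR/FNR and is flagged in the
#'   `tpr_defined` column.
#' @export
group_rates <- function(eligible, labels, group) {
  stopifnot(length(eligible) == length(labels),
            length(labels) == length(group),
            all(eligible %in% c(0, 1)), all(labels %in% c(0, 1)))
  g <- droplevels(factor(group))
  out <- lapply(levels(g), function(lev) {
    sel <- g == lev
    e <- eligible[sel]; y <- labels[sel]
    tp <- sum(e == 1 & y == 1); fn <- sum(e == 0 & y == 1)
    fp <- sum(e == 1 & y == 0); tn <- sum(e == 0 & y == 0)
    data.frame(group = lev, tp = tp, fn = fn, fp = fp, tn = tn,
               n = sum(sel),
               tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
               fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
               tpr_defined = tp + fn > 0)
  })
  structure(do.call(rbind, out), class = c("group_rates", "data.frame"))
}

#' Equal opportunity difference
#'
#' The TPR gap between two groups: `TPR(first) - TPR(second)` where the
#' default order is `c("black", "white")`, so a positive EOD means the white
#' group is the under-served (lower-TPR) group.
#'
#' @param rates a `group_rates` object covering both groups.
#' @param order length-2 character vector fixing the group order of the
#'   difference.
#' @return EOD in [-1, 1].
#' @export
eod <- function(rates, order = c("black", "white")) {
  stopifnot(inherits(rates, "group_rates"), length(order) == 2)
  idx <- match(order, rates$group)
  if (anyNA(idx)) {
    stop("groups not found in rates: ",
         paste(order[is.na(idx)], collapse = ", "))
  }
  tpr <- rates$tpr[idx]
  if (anyNA(tpr)) {
    stop("TPR undefined (no positive labels) for group(s): ",
         paste(order[is.na(tpr)], collapse = ", "))
  }
  tpr[1] - tpr[2]
}

#' One-sample t-test on an EOD series
#'
#' Tests H0: mean EOD = 0 against a two-sided alternative across folds or
#' bootstrap replicates, and reports the mean with a percentile 95% CI of
#' the series. A zero-variance series is handled explicitly: statistic 0 /
#' p = 1 when the constant is zero, |t| = Inf / p = 0 otherwise, both
#' flagged degenerate.
#'
#' @param series numeric EOD values, length >= 2.
#' @param level CI level for the percentile interval.
#' @return A `comparison_result` with `mean` and `ci`.
#' @export
eod_ttest <- function(series, level = 0.95) {
  stopifnot(length(series) >= 2, all(is.finite(series)))
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(series, c(a, 1 - a), type = 7))
  m <- mean(series)
  if (stats::sd(series) == 0) {
    stat <- if (m == 0) 0 else sign(m) * Inf
    return(comparison_result("one-sample t (EOD)", stat,
                             p = if (m == 0) 1 else 0,
                             n = length(series), mean = m, ci = ci,
                             degenerate = TRUE))
  }
  tt <- stats::t.test(series, mu = 0)
  comparison_result("one-sample t (EOD)", unname(tt$statistic),
                    p = tt$p.value, n = length(series), mean = m, ci = ci,
                    degenerate = FALSE)
}

#' Hedges' g for repeated measures
#'
#' Bias-corrected standardized mean difference for paired series:
#' `d_rm = mean(x - y) / sd(x - y) * sqrt(2 (1 - r))` with
#' `r = cor(x, y)`, multiplied by the small-sample correction
#' `J = 1 - 3 / (4 (n - 1) - 1)`. Values near 0.2 / 0.5 / 0.8 mark small /
#' moderate / large effects. When `x - y` is exactly constant with equal
#' spreads (r = 1), the algebraic limit `mean(x - y) / sd(x)` is used.
#'
#' @param x,y paired numeric series of equal length n >= 3.
#' @return Hedges' g (repeated measures).
#' @export
hedges_g_rm <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  d <- x - y
  sx <- stats::sd(x); sy <- stats::sd(y); sd_d <- stats::sd(d)
  if (sx == 0 && sy == 0) stop("zero variance in both series")
  correction <- 1 - 3 / (4 * (n - 1) - 1)
  if (sd_d < 1e-14) {
    # x - y constant: r = 1 and equal spreads; use the algebraic limit
    return(correction * mean(d) / sx)
  }
  r <- if (sx == 0 || sy == 0) 0 else stats::cor(x, y)
  correction * mean(d) / sd_d * sqrt(2 * (1 - r))
}

#' Common-language effect size for paired series
#'
#' The probability that a randomly chosen paired difference favors `x`,
#' computed under the normal model for the differences:
#' `pnorm(|mean(x - y)| / sd(x - y))`. 0.5 means no separation.
#'
#' @param x,y paired numeric series of equal length n >= 2.
#' @return A probability in [0.5, 1] (1 when the differences are a nonzero
#'   constant, 0.5 when identically zero).
#' @export
cl_effect_size <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) return(if (mean(d) != 0) 1 else 0.5)
  stats::pnorm(abs(mean(d)) / sd_d)
}

#' McNemar's test on paired classifier correctness
#'
#' Compares two classifiers evaluated on the same rows via their discordant
#' pairs: `b` = rows only classifier A gets right, `c` = rows only B gets
#' right. The reported statistic is the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)`; the p-value uses the exact binomial test
#' when `b + c < 25` (method `"auto"`). Zero discordance yields a flagged
#' no-test result.
#'
#' @param correct_a,correct_b 0/1 (or logical) correctness vectors of equal
#'   length.
#' @param method `"auto"`, `"exact"` or `"chisq"`.
#' @return A `comparison_result` with `b`, `c` and `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b,
                         method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  a <- as.integer(correct_a); b_vec <- as.integer(correct_b)
  stopifnot(length(a) == length(b_vec), all(a %in% 0:1), all(b_vec %in% 0:1))
  b <- sum(a == 1 & b_vec == 0)
  cc <- sum(a == 0 & b_vec == 1)
  nd <- b + cc
  if (nd == 0) {
    return(comparison_result("McNemar", NA_real_, p = NA_real_,
                             n = length(a), b = b, c = cc,
                             method = "none", degenerate = TRUE))
  }
  stat <- (abs(b - cc) - 1)^2 / nd
  use_exact <- method == "exact" || (method == "auto" && nd < 25)
  p <- if (use_exact) {
    min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
  } else {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  comparison_result("McNemar", stat, p = p, n = length(a), b = b, c = cc,
                    method = if (use_exact) "exact" else "chisq",
                    degenerate = FALSE)
}

# Placement values (structural components) of scores against the opposite
# class: for each positive, the fraction of negatives it outranks (ties
# 1/2), and vice versa.
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sn <- sort(neg); sp <- sort(pos)
  le_n <- findInterval(pos, sn)                   # negatives <= each positive
  lt_n <- findInterval(pos, sn, left.open = TRUE) # negatives <  each positive
  v10 <- (lt_n + 0.5 * (le_n - lt_n)) / length(neg)
  le_p <- findInterval(neg, sp)
  lt_p <- findInterval(neg, sp, left.open = TRUE)
  v01 <- ((length(pos) - le_p) + 0.5 * (le_p - lt_p)) / length(pos)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same rows. AUCs
#' are Mann-Whitney rank statistics; the covariance of the correlated AUCs
#' comes from the placement-value (structural-component) construction, and
#' the difference is referred to a two-sided normal test.
#'
#' @param scores_a,scores_b paired score vectors on identical rows.
#' @param labels 0/1 outcome labels, both classes present.
#' @return A `comparison_result` with `auc` (both models), `auc_diff` and
#'   `variance`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels), all(labels %in% c(0, 1)))
  if (!all(c(0, 1) %in% labels)) stop("both outcome classes must be present")
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (!is.finite(v) || v <= 0) {
    return(comparison_result("DeLong", statistic = 0,
                             p = if (diff == 0) 1 else NA_real_,
                             n = c(pos = m, neg = n),
                             auc = c(a = pa$auc, b = pb$auc),
                             auc_diff = diff, variance = v,
                             degenerate = TRUE))
  }
  z <- diff / sqrt(v)
  comparison_result("DeLong", statistic = z, p = 2 * stats::pnorm(-abs(z)),
                    n = c(pos = m, neg = n),
                    auc = c(a = pa$auc, b = pb$auc),
                    auc_diff = diff, variance = v, degenerate = FALSE)
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples rows with replacement within strata (by default the outcome, so
#' every replicate keeps the class counts of the original data), evaluates
#' the statistic per replicate and returns the percentile interval.
#' Replicates on which the statistic fails are dropped and counted.
#'
#' @param statistic function taking a data.frame and returning a scalar.
#' @param data a data.frame.
#' @param n_reps number of bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @param strata stratification vector; defaults to `data$outcome`.
#' @return A list with `lo`, `hi`, `estimates`, `n_failed`.
#' @export
stratified_bootstrap_ci <- function(statistic, data, n_reps = 1000,
                                    level = 0.95, seed = 1L,
                                    strata = data$outcome) {
  stopifnot(n_reps >= 100, is.function(statistic))
  strata <- as.factor(strata)
  by_stratum <- split(seq_len(nrow(data)), strata)
  estimates <- with_local_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      idx <- unlist(lapply(by_stratum, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      tryCatch(statistic(data[idx, , drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(estimates))
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0) stop("statistic failed on every bootstrap replicate")
  a <- (1 - level) / 2
  q <- unname(stats::quantile(est, c(a, 1 - a), type = 7))
  list(lo = q[1], hi = q[2], estimates = estimates, n_failed = n_failed,
       level = level)
}

ks_distance <- function(z) {
  # z: sorted standardized sample; distance to the standard normal CDF
  n <- length(z)
  f <- stats::pnorm(z)
  i <- seq_len(n)
  max(i / n - f, f - (i - 1) / n)
}

#' Kolmogorov-Smirnov normality check with estimated parameters
#'
#' KS distance of a series against a normal with the sample mean and SD.
#' Because the parameters are estimated, the naive KS p-value is
#' anti-conservative; the p-value is instead calibrated by Monte-Carlo
#' simulation of the null distribution of the distance (Lilliefors-style),
#' which is parameter-free for the normal family.
#'
#' @param series numeric series, length >= 5, non-constant.
#' @param n_mc Monte-Carlo replicates for the null distribution.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return A `comparison_result` (statistic = KS distance).
#' @export
ks_normality <- function(series, n_mc = 2000L, seed = 1L) {
  n <- length(series)
  stopifnot(n >= 5)
  s <- stats::sd(series)
  if (s == 0) stop("constant series: normality check undefined")
  d_obs <- ks_distance(sort((series - mean(series)) / s))
  d_null <- with_local_seed(seed, {
    vapply(seq_len(n_mc), function(r) {
      z <- stats::rnorm(n)
      ks_distance(sort((z - mean(z)) / stats::sd(z)))
    }, numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_mc + 1)
  comparison_result("KS normality (Lilliefors MC)", d_obs, p = p, n = n,
                    n_mc = n_mc)
}
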