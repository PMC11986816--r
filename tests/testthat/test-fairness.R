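test_that("group rates reproduce hand-counted confusion matrices", {
  eligible <- c(1, 1, 0, 0, 1, 0, 1, 1, 0, 0)
  labels   <- c(1, 0, 1, 0, 1, 1, 0, 1, 0, 0)
  group    <- c("b", "b", "b", "b", "b", "w", "w", "w", "w", "w")
  r <- group_rates(eligible, labels, group)
  b <- r[r$group == "b", ]; w <- r[r$group == "w", ]
  expect_equal(c(b$tp, b$fn, b$fp, b$tn), c(2, 1, 1, 1))
  expect_equal(c(w$tp, w$fn, w$fp, w$tn), c(1, 1, 1, 2))
  expect_equal(b$tpr, 2 / 3); expect_equal(b$fnr, 1 / 3)
  expect_equal(w$specificity, 2 / 3)
  expect_equal(r$tpr + r$fnr, c(1, 1))
  # all-negative predictions: TPR 0, specificity 1
  r0 <- group_rates(rep(0, 10), labels, group)
  expect_equal(r0$tpr, c(0, 0)); expect_equal(r0$specificity, c(1, 1))
  # a group without positives is flagged
  rf <- group_rates(c(1, 0), c(0, 0), c("b", "w"))
  expect_true(all(is.na(rf$tpr)))
  expect_false(any(rf$tpr_defined))
})

test_that("EOD is the signed race TPR gap and antisymmetric under order swap", {
  eligible <- c(1, 1, 0, 1, 0, 0)
  labels   <- c(1, 1, 1, 1, 1, 1)
  group    <- c("black", "black", "black", "white", "white", "white")
  r <- group_rates(eligible, labels, group)
  expect_equal(eod(r), 2 / 3 - 1 / 3)
  expect_equal(eod(r, order = c("white", "black")), -(2 / 3 - 1 / 3))
  same <- group_rates(c(1, 0, 1, 0), c(1, 1, 1, 1),
                      c("black", "black", "white", "white"))
  expect_equal(eod(same), 0)
  rf <- group_rates(c(1, 0), c(1, 0), c("black", "white"))
  expect_error(eod(rf), "TPR undefined")
})

test_that("the one-sample EOD t-test matches the closed form", {
  s <- c(0.01, 0.02, 0.03, 0.02)
  res <- eod_ttest(s)
  expect_equal(res$statistic, 4.89897948557, tolerance = 1e-9)
  expect_equal(res$p, 0.0162766034594, tolerance = 1e-9)
  expect_equal(res$mean, 0.02)
  zero <- eod_ttest(rep(0, 5))
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p, 1)
  expect_true(zero$degenerate)
  const <- eod_ttest(rep(0.1, 5))
  expect_equal(const$p, 0)
  expect_true(is.infinite(const$statistic))
})

test_that("Hedges g_rm matches independent formula evaluations", {
  x <- c(0.85, 0.82, 0.88, 0.90, 0.86)
  y <- c(0.80, 0.79, 0.84, 0.88, 0.85)
  expect_equal(hedges_g_rm(x, y), 0.649175748956, tolerance = 1e-9)
  expect_equal(hedges_g_rm(y, x), -0.649175748956, tolerance = 1e-9)
  expect_equal(hedges_g_rm(x, x), 0)
  # constant shift: the r = 1 algebraic limit J * c / sd(x)
  yy <- c(0.70, 0.75, 0.80, 0.72, 0.78)
  expect_equal(hedges_g_rm(yy + 0.04, yy), 0.776114000116, tolerance = 1e-9)
  expect_error(hedges_g_rm(rep(1, 5), rep(0, 5)), "zero variance")
})

test_that("the CL effect size is the normal probability of a favorable difference", {
  a <- c(0.9, 0.7, 0.8, 0.6); b <- c(0.85, 0.72, 0.7, 0.55)
  expect_equal(cl_effect_size(a, b), 0.819180241255, tolerance = 1e-9)
  expect_equal(cl_effect_size(a, a), 0.5)
  # standardized mean difference of exactly 1 maps to pnorm(1)
  set.seed(71)
  d <- rnorm(200)
  d <- (d - mean(d)) / sd(d) + 1  # mean 1, sd 1
  expect_equal(cl_effect_size(d, rep(0, 200)), pnorm(1), tolerance = 1e-12)
  expect_equal(cl_effect_size(c(1, 1), c(0, 0)), 1)
})

test_that("McNemar reports the continuity-corrected statistic with exact small-sample p", {
  mk <- function(b, c, both = 10) {
    list(a = c(rep(1, b), rep(0, c), rep(1, both)),
         b = c(rep(0, b), rep(1, c), rep(1, both)))
  }
  v <- mk(5, 15)
  res <- mcnemar_test(v$a, v$b)
  expect_equal(res$statistic, 4.05)
  expect_equal(res$method, "exact")
  expect_equal(res$p, 2 * pbinom(5, 20, 0.5), tolerance = 1e-12)
  # forced chi-square path agrees with stats::mcnemar.test
  res_chi <- mcnemar_test(v$a, v$b, method = "chisq")
  ref <- mcnemar.test(matrix(c(10, 15, 5, 0), 2))
  expect_equal(res_chi$statistic, unname(ref$statistic))
  expect_equal(res_chi$p, ref$p.value, tolerance = 1e-12)
  # single discordant pair: exact two-sided p = 1
  v1 <- mk(1, 0)
  expect_equal(mcnemar_test(v1$a, v1$b)$p, 1)
  # identical classifiers: flagged no-test
  same <- mcnemar_test(c(1, 0, 1), c(1, 0, 1))
  expect_true(same$degenerate)
  expect_true(is.na(same$p))
})

test_that("DeLong AUCs equal pair counting and identical scores give p = 1", {
  set.seed(72)
  scores <- c(0.1, 0.2, 0.2, 0.3, 0.5, 0.5, 0.5, 0.6, 0.7, 0.8, 0.9, 0.9)
  labels <- c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 0, 1)
  other <- runif(12)
  res <- delong_test(scores, other, labels)
  expect_equal(unname(res$auc["a"]), concordance_auc(scores, labels),
               tolerance = 1e-12)
  expect_equal(unname(res$auc["b"]), concordance_auc(other, labels),
               tolerance = 1e-12)
  same <- delong_test(scores, scores, labels)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
})

test_that("DeLong agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  n <- 250
  lp <- rnorm(n)
  labels <- rbinom(n, 1, plogis(lp))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
  a <- lp + rnorm(n, sd = 0.8)
  b <- lp + rnorm(n, sd = 1.4)
  res <- delong_test(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(res$statistic), unname(ref$statistic), tolerance = 1e-9)
})

test_that("stratified bootstrap preserves class counts and is seeded", {
  set.seed(74)
  d <- data.frame(x = rnorm(200), outcome = rep(c(0, 1), c(160, 40)))
  counts <- stratified_bootstrap_ci(function(dd) {
    expect_equal(sum(dd$outcome), 40)  # class counts preserved per replicate
    mean(dd$x)
  }, d, n_reps = 100, seed = 5)
  ci2 <- stratified_bootstrap_ci(function(dd) mean(dd$x), d,
                                 n_reps = 100, seed = 5)
  expect_equal(counts$estimates, ci2$estimates)
  const <- stratified_bootstrap_ci(function(dd) 7, d, n_reps = 100, seed = 1)
  expect_equal(const$lo, 7); expect_equal(const$hi, 7)
  # failed replicates are dropped and counted
  flaky <- local({
    k <- 0
    function(dd) { k <<- k + 1; if (k <= 3) stop("boom") else mean(dd$x) }
  })
  res <- stratified_bootstrap_ci(flaky, d, n_reps = 100, seed = 2)
  expect_equal(res$n_failed, 3)
})

test_that("bootstrap intervals for a mean attain near-nominal coverage", {
  set.seed(75)
  hits <- 0
  for (i in 1:150) {
    d <- data.frame(x = rnorm(50, mean = 2), outcome = rep(c(0, 1), 25))
    ci <- stratified_bootstrap_ci(function(dd) mean(dd$x), d,
                                  n_reps = 200, seed = i)
    hits <- hits + (ci$lo <= 2 && 2 <= ci$hi)
  }
  expect_gt(hits / 150, 0.85)
  expect_lt(hits / 150, 0.995)
})

test_that("the KS distance matches a manual max-gap computation", {
  x <- c(-1.1, -0.4, 0.2, 0.8, 1.6)
  z <- sort((x - mean(x)) / sd(x))
  f <- pnorm(z)
  manual <- max(pmax((1:5) / 5 - f, f - (0:4) / 5))
  expect_equal(fairscreen:::ks_distance(z), manual, tolerance = 1e-14)
})

test_that("the normality check rejects bimodal data and passes normal data", {
  set.seed(76)
  bim <- c(rnorm(100, -3), rnorm(100, 3))
  expect_lt(ks_normality(bim, n_mc = 500, seed = 1)$p, 0.05)
  norm <- rnorm(200)
  expect_gt(ks_normality(norm, n_mc = 500, seed = 1)$p, 0.01)
  expect_error(ks_normality(rep(1, 10)), "constant")
  # seeded: identical p on repeat
  expect_equal(ks_normality(norm, n_mc = 200, seed = 9)$p,
               ks_normality(norm, n_mc = 200, seed = 9)$p)
})
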