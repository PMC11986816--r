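test_that("balanced under-sampling keeps all minority rows and an equal majority draw", {
  y <- c(rep(0, 1000), rep(1, 40))
  idx <- undersample_balanced(y, seed = 3)
  expect_length(idx, 80)
  expect_equal(sum(y[idx] == 1), 40)
  expect_equal(sum(y[idx] == 0), 40)
  expect_true(all(which(y == 1) %in% idx))
  expect_identical(idx, undersample_balanced(y, seed = 3))
  expect_false(identical(idx, undersample_balanced(y, seed = 4)))
  # already balanced: every row is returned
  yb <- rep(c(0, 1), 25)
  expect_identical(undersample_balanced(yb, seed = 1), seq_along(yb))
  expect_error(undersample_balanced(rep(1, 10), seed = 1), "both outcome")
})

test_that("boosting drives training error to zero on separable data", {
  x <- data.frame(v = c(1, 2, 3, 4, 10, 11, 12, 13))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_adaboost(x, y, config = eec_config(n_weak = 5))
  expect_lte(length(fit$trees), 2)
  pred <- as.integer(predict(fit$trees[[1]], x, type = "class") == "1")
  expect_equal(pred, y)
  # perfect learner's stage coefficient is capped, not infinite
  expect_true(all(is.finite(fit$alphas)))
  expect_error(fit_adaboost(x, rep(1, 8), config = eec_config()),
               "single class")
})

test_that("stage coefficients follow the boosting recurrence exactly", {
  set.seed(22)
  n <- 60
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x$a + 0.8 * rnorm(n) > 0)
  w0 <- runif(n, 0.5, 2)
  cfg <- eec_config(n_weak = 6, learning_rate = 0.3)
  fit <- fit_adaboost(x, y, weights = w0, config = cfg)
  expect_gte(length(fit$trees), 3)
  # independently re-run the recurrence from the fitted weak learners
  ys <- ifelse(y == 1, 1, -1)
  w <- w0 / sum(w0)
  for (m in seq_along(fit$trees)) {
    h <- ifelse(predict(fit$trees[[m]], x, type = "class") == "1", 1, -1)
    eps <- sum(w[h != ys])
    alpha <- 0.3 * log((1 - eps) / eps)
    expect_equal(fit$alphas[m], alpha, tolerance = 1e-12)
    w <- w * exp(alpha * (h != ys))
    w <- w / sum(w)
  }
})

test_that("boosting is invariant to the scale of the initial weights", {
  set.seed(31)
  x <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- rbinom(40, 1, plogis(x$a))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  w <- runif(40, 0.2, 3)
  f1 <- fit_adaboost(x, y, weights = w, config = eec_config(n_weak = 4))
  f2 <- fit_adaboost(x, y, weights = 2 * w, config = eec_config(n_weak = 4))
  expect_equal(f1$alphas, f2$alphas, tolerance = 1e-12)
})

test_that("risk scores are bounded, deterministic and aggregate sub-ensembles", {
  set.seed(41)
  co <- generate_cohort(sim_config(n = 2500, seed = 55))
  feats <- default_model_features()
  cfg <- eec_config(n_subsets = 2, n_weak = 5, seed = 17)
  model <- fit_easy_ensemble(co, feats, config = cfg)
  s <- predict_risk(model, co)
  expect_true(all(s >= 0 & s <= 1))
  model2 <- fit_easy_ensemble(co, feats, config = cfg)
  expect_equal(predict_risk(model2, co), s)
  # n_subsets = 1 equals its single sub-ensemble's mapped margin
  cfg1 <- eec_config(n_subsets = 1, n_weak = 5, seed = 17)
  m1 <- fit_easy_ensemble(co, feats, config = cfg1)
  margin <- fairscreen:::adaboost_margin(m1$sub_ensembles[[1]], co[feats])
  expect_equal(predict_risk(m1, co), (margin + 1) / 2, tolerance = 1e-12)
  expect_error(predict_risk(model, co[, 1:3]), "lacks model features")
})

test_that("a hand-aggregated two-stump ensemble matches predict_risk", {
  # two sub-ensembles of one stump each: the score must equal the mean of
  # the two stumps' 0/1 votes
  set.seed(43)
  co <- generate_cohort(sim_config(n = 1200, seed = 77))
  feats <- c("age", "pack_years")
  model <- fit_easy_ensemble(co, feats,
                             config = eec_config(n_subsets = 2, n_weak = 1,
                                                 seed = 5))
  votes <- vapply(model$sub_ensembles, function(sub) {
    as.numeric(predict(sub$trees[[1]], co[feats], type = "class") == "1")
  }, numeric(nrow(co)))
  expect_equal(predict_risk(model, co), rowMeans(votes), tolerance = 1e-12)
})

test_that("every sub-ensemble trains on an exactly balanced set", {
  co <- generate_cohort(sim_config(n = 3000, seed = 91))
  model <- fit_easy_ensemble(co, c("age", "pack_years", "copd"),
                             config = eec_config(n_subsets = 4, n_weak = 3,
                                                 seed = 2))
  for (sub in model$sub_ensembles) {
    y <- co$outcome[sub$index]
    expect_equal(sum(y == 1), sum(y == 0))
  }
})

test_that("weighted logistic equals glm under unit weights and respects weight semantics", {
  set.seed(51)
  n <- 300
  co <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  co$outcome <- rbinom(n, 1, plogis(0.8 * co$x1 - 0.4 * co$x2))
  fit <- fit_weighted_logistic(co, c("x1", "x2"))
  ref <- glm(outcome ~ x1 + x2, binomial(), co)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_false(fit$ridged)
  # duplicating a row is the same as doubling its weight
  dup <- rbind(co, co[1:30, ])
  f_dup <- fit_weighted_logistic(dup, c("x1", "x2"))
  w <- rep(1, n); w[1:30] <- 2
  f_w <- fit_weighted_logistic(co, c("x1", "x2"), weights = w)
  expect_equal(f_dup$coefficients, f_w$coefficients, tolerance = 1e-7)
  p <- predict_risk(fit, co)
  expect_equal(p, unname(fitted(ref)), tolerance = 1e-8)
})

test_that("weighted logistic maximizes the weighted likelihood (grid oracle)", {
  co <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2),
                   outcome = c(0, 0, 1, 0, 1, 1))
  w <- c(1, 2, 1, 1, 2, 1)
  fit <- fit_weighted_logistic(co, "x", weights = w)
  wll <- function(b0, b1) {
    p <- plogis(b0 + b1 * co$x)
    sum(w * (co$outcome * log(p) + (1 - co$outcome) * log(1 - p)))
  }
  # two-stage grid maximization
  grid <- expand.grid(b0 = seq(-3, 3, 0.05), b1 = seq(-1, 5, 0.05))
  ll <- mapply(wll, grid$b0, grid$b1)
  best <- grid[which.max(ll), ]
  fine <- expand.grid(b0 = seq(best$b0 - 0.06, best$b0 + 0.06, 0.002),
                      b1 = seq(best$b1 - 0.06, best$b1 + 0.06, 0.002))
  llf <- mapply(wll, fine$b0, fine$b1)
  bestf <- fine[which.max(llf), ]
  expect_equal(unname(fit$coefficients[1]), bestf$b0, tolerance = 5e-3)
  expect_equal(unname(fit$coefficients[2]), bestf$b1, tolerance = 5e-3)
})

test_that("separated data falls back to a converged ridge fit", {
  co <- data.frame(x = c(-3, -2, -1, 1, 2, 3),
                   outcome = c(0, 0, 0, 1, 1, 1))
  fit <- fit_weighted_logistic(co, "x")
  expect_true(fit$ridged)
  expect_true(fit$converged)
  p <- predict_risk(fit, co)
  expect_true(all(p[co$outcome == 1] > 0.5) && all(p[co$outcome == 0] < 0.5))
})

test_that("the full-scale ensemble configuration runs end to end", {
  co <- generate_cohort(sim_config(n = 1500, seed = 303))
  model <- fit_easy_ensemble(co, default_model_features(),
                             config = eec_config(seed = 8))  # 70 x 200
  expect_length(model$sub_ensembles, 70)
  s <- predict_risk(model, co[1:200, ])
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(sd(s), 0)
  path <- tempfile(fileext = ".json")
  write_eec_model(model, path)
  expect_true(file.size(path) > 0)
  unlink(path)
})

test_that("balancing rescues minority-class recall lost by unbalanced boosting", {
  # at ~4% prevalence a single boosted model trained on the full unbalanced
  # data essentially never calls the minority class at its native decision
  # threshold; the balanced ensemble does
  feats <- default_model_features()
  for (s in 1:3) {
    train <- generate_cohort(sim_config(n = 6000, seed = 400 + s))
    test <- generate_cohort(sim_config(n = 6000, seed = 500 + s))
    eec <- fit_easy_ensemble(train, feats,
                             config = eec_config(n_subsets = 10, n_weak = 30,
                                                 seed = s))
    single <- fit_adaboost(train[feats], train$outcome,
                           config = eec_config(n_weak = 30, seed = s))
    sub <- list(trees = single$trees, alphas = single$alphas)
    rec_eec <- mean(predict_risk(eec, test)[test$outcome == 1] >= 0.5)
    sc <- (fairscreen:::adaboost_margin(sub, test[feats]) + 1) / 2
    rec_single <- mean(sc[test$outcome == 1] >= 0.5)
    expect_gt(rec_eec, rec_single)
    expect_gt(rec_eec, 0.5)
    expect_lt(rec_single, 0.2)
  }
})
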