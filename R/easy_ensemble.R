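# Easy-ensemble classifier ----------------------------------------------------
#
# The risk model for heavily imbalanced outcomes: many balanced random
# under-samples of the majority class, each boosted with weight-aware
# decision stumps (AdaBoost with learning-rate shrinkage), scores averaged
# across sub-ensembles. Pre-processing reweighing weights enter as the
# boosting rounds' initial instance weights; they do not alter the sampling.

#' Easy-ensemble hyperparameters
#'
#' @param n_subsets number of balanced sub-ensembles (the tuned operating
#'   point of the full-scale model is 70).
#' @param n_weak boosting rounds (weak learners) per sub-ensemble (tuned
#'   full-scale value 200).
#' @param learning_rate shrinkage applied to every stage coefficient
#'   (tuned full-scale value 0.1).
#' @param weak_learner_depth maximum depth of each tree; 1 = decision stump.
#' @param seed integer seed governing the under-samples.
#' @return An object of class `eec_config`.
#' @export
eec_config <- function(n_subsets = 70L, n_weak = 200L, learning_rate = 0.1,
                       weak_learner_depth = 1L, seed = 1L) {
  stopifnot(n_subsets >= 1, n_weak >= 1, learning_rate > 0,
            weak_learner_depth >= 1)
  structure(list(n_subsets = as.integer(n_subsets),
                 n_weak = as.integer(n_weak),
                 learning_rate = learning_rate,
                 weak_learner_depth = as.integer(weak_learner_depth),
                 seed = as.integer(seed)),
            class = "eec_config")
}

#' Balanced random under-sample of the majority class
#'
#' Returns the indices of all minority-class rows plus an equally sized
#' uniform random subset (without replacement) of majority-class rows.
#' Sampling probability is uniform regardless of any instance weights.
#'
#' @param y binary outcome vector (0/1).
#' @param seed integer seed.
#' @return Integer row indices (minority rows first).
#' @export
undersample_balanced <- function(y, seed) {
  stopifnot(all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  minority_class <- if (n1 <= n0) 1 else 0
  min_idx <- which(y == minority_class)
  maj_idx <- which(y != minority_class)
  if (length(min_idx) == length(maj_idx)) return(seq_along(y))
  keep <- with_local_seed(seed, sample(maj_idx, length(min_idx)))
  c(min_idx, sort(keep))
}

max_stage_coefficient <- function(learning_rate) learning_rate * log(1e10)

#' Fit one boosted sub-ensemble (AdaBoost with shrinkage)
#'
#' Discrete adaptive boosting on a (balanced) training set: initialize
#' instance weights proportional to `weights`, then per round fit a
#' depth-limited classification tree on the current weights, compute the
#' weighted error `e`, stage coefficient `a = learning_rate * log((1-e)/e)`,
#' multiply misclassified instances' weights by `exp(a)` and renormalize.
#' Boosting stops early when `e >= 0.5` (learner discarded), when the tree
#' cannot split, or when `e = 0` (perfect learner kept with its stage
#' coefficient capped at `learning_rate * log(1e10)` for numerical safety).
#'
#' @param x data.frame of features.
#' @param y binary outcome (0/1), both classes present.
#' @param weights positive initial instance weights; scale-invariant
#'   (weights are normalized to sum 1 before the first round).
#' @param config an [eec_config()]; only `n_weak`, `learning_rate` and
#'   `weak_learner_depth` are used.
#' @return A list with `trees`, `alphas` and the feature schema.
#' @export
fit_adaboost <- function(x, y, weights = NULL, config = eec_config()) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("degenerate training set: single class")
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  w <- weights / sum(weights)
  yf <- factor(y, levels = c(0, 1))
  ys <- ifelse(y == 1, 1, -1)
  dat <- cbind(x, .y = yf)
  ctrl <- rpart::rpart.control(maxdepth = config$weak_learner_depth,
                               cp = -1, minsplit = 2, minbucket = 1,
                               xval = 0, maxcompete = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(config$n_weak)) {
    tree <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                         control = ctrl)
    if (nrow(tree$frame) == 1L) break  # no usable split left
    pred <- ifelse(predict(tree, dat, type = "class") == "1", 1, -1)
    miss <- pred != ys
    eps <- sum(w[miss])
    if (eps >= 0.5) break
    if (eps <= 0) {
      trees[[length(trees) + 1L]] <- tree
      alphas <- c(alphas, max_stage_coefficient(config$learning_rate))
      break
    }
    alpha <- config$learning_rate * log((1 - eps) / eps)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas, features = names(x))
}

# Normalized boosted margin of one sub-ensemble, in [-1, 1].
adaboost_margin <- function(sub, newdata) {
  if (length(sub$trees) == 0) return(rep(0, nrow(newdata)))
  votes <- vapply(sub$trees, function(tree) {
    ifelse(predict(tree, newdata, type = "class") == "1", 1, -1)
  }, numeric(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  drop(votes %*% sub$alphas) / sum(sub$alphas)
}

#' Fit an easy-ensemble classifier
#'
#' Draws `n_subsets` independent balanced under-samples (sub-ensemble `i`
#' seeded with `seed + i`) and boosts each with [fit_adaboost()], carrying
#' the rows' instance weights (e.g. from [reweigh()]) as the boosting
#' rounds' initial weights.
#'
#' @param cohort a data.frame containing the features and outcome.
#' @param features character vector of model feature columns.
#' @param outcome name of the binary outcome column.
#' @param weights optional positive instance weights (one per cohort row);
#'   when absent, a `.weight` column is used if present, else unit weights.
#' @param config an [eec_config()].
#' @return An object of class `eec_model` with a [predict_risk()] method.
#' @export
fit_easy_ensemble <- function(cohort, features, outcome = "outcome",
                              weights = NULL, config = eec_config()) {
  stopifnot(all(features %in% names(cohort)))
  y <- cohort[[outcome]]
  stopifnot(all(y %in% c(0, 1)))
  if (is.null(weights)) {
    weights <- if (".weight" %in% names(cohort)) cohort$.weight
               else rep(1, nrow(cohort))
  }
  x <- cohort[features]
  subs <- vector("list", config$n_subsets)
  for (i in seq_len(config$n_subsets)) {
    idx <- undersample_balanced(y, seed = substream(config$seed, i))
    subs[[i]] <- fit_adaboost(x[idx, , drop = FALSE], y[idx],
                              weights = weights[idx], config = config)
    subs[[i]]$index <- idx
  }
  structure(list(sub_ensembles = subs, features = features,
                 outcome = outcome, config = config),
            class = "eec_model")
}

#' Predict risk scores
#'
#' @param model a fitted risk model (`eec_model` or `weighted_logistic`).
#' @param newdata data.frame of rows conforming to the model's schema.
#' @return Numeric risk scores in [0, 1].
#' @export
predict_risk <- function(model, newdata) UseMethod("predict_risk")

#' @describeIn predict_risk mean over sub-ensembles of the normalized
#'   boosted margin mapped to [0, 1].
#' @export
predict_risk.eec_model <- function(model, newdata) {
  missing <- setdiff(model$features, names(newdata))
  if (length(missing)) {
    stop("newdata lacks model features: ", paste(missing, collapse = ", "))
  }
  x <- newdata[model$features]
  margins <- vapply(model$sub_ensembles, adaboost_margin,
                    numeric(nrow(x)), newdata = x)
  margins <- matrix(margins, nrow = nrow(x))
  (rowMeans(margins) + 1) / 2
}

#' @export
predict.eec_model <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Weighted logistic risk model
#'
#' Maximum weighted-likelihood logistic regression, the baseline risk model.
#' Weights have frequency semantics: duplicating a row is equivalent to
#' doubling its weight. When the IRLS fit does not converge or the data are
#' (quasi-)separated, the model refits with a small ridge penalty
#' (`lambda = 1e-6` per observation on non-intercept coefficients) and
#' records that it did so.
#'
#' @param cohort data.frame with the features and outcome.
#' @param features character vector of model feature columns.
#' @param outcome name of the binary outcome column.
#' @param weights optional positive instance weights (default: `.weight`
#'   column if present, else unit weights).
#' @param max_iter IRLS iteration cap before the fit is declared
#'   non-convergent.
#' @return An object of class `weighted_logistic`.
#' @export
fit_weighted_logistic <- function(cohort, features, outcome = "outcome",
                                  weights = NULL, max_iter = 100L) {
  stopifnot(all(features %in% names(cohort)))
  y <- cohort[[outcome]]
  stopifnot(all(y %in% c(0, 1)))
  if (is.null(weights)) {
    weights <- if (".weight" %in% names(cohort)) cohort$.weight
               else rep(1, nrow(cohort))
  }
  stopifnot(length(weights) == nrow(cohort), all(weights > 0))
  dat <- cbind(cohort[features], .y = y)
  form <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               weights = weights, control = list(maxit = max_iter)),
    warning = function(w) {
      # weighted likelihoods legitimately have non-integer "successes";
      # separation warnings are handled via the ridge fallback below
      if (grepl("non-integer|fitted probabilities", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mm <- stats::model.matrix(fit)
  ridged <- FALSE
  beta <- stats::coef(fit)
  if (!fit$converged || anyNA(beta) || max(abs(beta[-1])) > 15) {
    beta <- ridge_logistic_irls(mm, y, weights, lambda = 1e-6 * nrow(mm),
                                max_iter = max_iter)
    ridged <- TRUE
  }
  structure(list(coefficients = beta, terms = stats::terms(fit),
                 xlevels = fit$xlevels, features = features,
                 outcome = outcome, ridged = ridged,
                 converged = fit$converged || ridged),
            class = "weighted_logistic")
}

# Newton-IRLS ridge logistic regression (penalty on non-intercept terms),
# used as the documented fallback under separation or non-convergence.
ridge_logistic_irls <- function(X, y, w, lambda, max_iter = 100L,
                                tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- pmax(w * mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, w * (y - mu))) - drop(pen %*% beta)
    hess <- crossprod(X, X * v) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  if (it == max_iter && max(abs(step)) >= 1e-6) {
    stop("weighted logistic fit failed to converge after ", max_iter,
         " iterations (max step ", format(max(abs(step))), ")")
  }
  stats::setNames(beta, colnames(X))
}

#' @describeIn predict_risk fitted probabilities of the weighted logistic
#'   model.
#' @export
predict_risk.weighted_logistic <- function(model, newdata) {
  missing <- setdiff(model$features, names(newdata))
  if (length(missing)) {
    stop("newdata lacks model features: ", paste(missing, collapse = ", "))
  }
  tt <- stats::delete.response(model$terms)
  mm <- stats::model.matrix(tt, data = newdata, xlev = model$xlevels)
  unname(drop(plogis(mm %*% model$coefficients)))
}

#' @export
predict.weighted_logistic <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Serialize an easy-ensemble model's structure to JSON
#'
#' Writes a versioned container with the configuration, per-sub-ensemble
#' stage coefficients and sampled indices, and a hash of the feature schema.
#' (Tree structure is summarised, not fully serialized.)
#'
#' @param model an `eec_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eec_model <- function(model, path) {
  payload <- list(
    format_version = 1L,
    config = unclass(model$config),
    schema = model$features,
    schema_hash = sum(utf8ToInt(paste(model$features, collapse = "|"))),
    sub_ensembles = lapply(model$sub_ensembles, function(s) {
      list(n_trees = length(s$trees), alphas = s$alphas, index = s$index)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
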