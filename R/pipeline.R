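# Training and testing protocol ----------------------------------------------
#
# Training: stratified k-fold cross-validated grid search over
# {no-reweigh, RW1 (race), RW2 (race x gender)} x {TU, TY} x model
# hyperparameters. Per fold, reweighing weights and thresholds are derived
# from the training folds only; the held-out fold contributes an AUC and an
# EOD. The selected configuration minimizes |mean EOD| among configurations
# whose predictive performance is not significantly below the best.
# Testing: the frozen model and threshold are evaluated on stratified
# resamples of the held-out split, yielding the accuracy and fairness
# report (sensitivity/specificity/F1, overall and per-race AUC, EOD series
# with t-test and effect sizes).

#' Default model feature set
#'
#' The selected cohort features plus race. Race is included as a model
#' covariate — as established lung cancer risk models do — so the outcome
#' bias that reweighing targets is learnable (and removable) by the model;
#' pass your own feature vector to exclude it.
#' @return Character vector of column names.
#' @export
default_model_features <- function() {
  c("age", "education_level", "bmi", "smoking_status", "pack_years",
    "years_smoked", "years_since_quit", "copd", "personal_health_history",
    "race")
}

preprocess_attributes <- function(preprocess) {
  switch(tolower(preprocess),
         none = NULL,
         rw1 = "race",
         rw2 = c("race", "gender"),
         stop("unknown preprocess option: ", preprocess))
}

#' Stratified k-fold assignment
#'
#' Shuffles each outcome class independently and deals rows round-robin, so
#' per-fold class counts differ by at most one row.
#'
#' @param y binary outcome vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer fold ids in `1:k`.
#' @export
stratified_kfold <- function(y, k = 10L, seed = 1L) {
  stopifnot(k >= 2)
  classes <- unique(y)
  small <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  if (any(small < k)) {
    stop("each outcome class needs at least k = ", k, " rows")
  }
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Grid specification for the training protocol
#'
#' @param preprocess subset of `c("none", "rw1", "rw2")`.
#' @param thresholds subset of `c("TU", "TY")`.
#' @param family `"EEC"` (easy ensemble) or `"LR"` (weighted logistic).
#' @param eec_configs list of [eec_config()] objects to search over (EEC
#'   family only; a single default is used when empty).
#' @param features model feature columns.
#' @param cv_folds number of cross-validation folds.
#' @param rule_version USPSTF rule year whose specificity anchors TU.
#' @param seed integer seed for fold assignment.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(preprocess = c("none", "rw1", "rw2"),
                      thresholds = c("TU", "TY"),
                      family = c("EEC", "LR"),
                      eec_configs = list(),
                      features = default_model_features(),
                      cv_folds = 10L,
                      rule_version = 2021,
                      seed = 1L) {
  family <- match.arg(family)
  preprocess <- match.arg(tolower(preprocess), c("none", "rw1", "rw2"),
                          several.ok = TRUE)
  thresholds <- match.arg(thresholds, c("TU", "TY"), several.ok = TRUE)
  stopifnot(length(preprocess) >= 1, length(thresholds) >= 1, cv_folds >= 2)
  if (family == "EEC" && length(eec_configs) == 0) {
    eec_configs <- list(eec_config())
  }
  if (family == "LR") eec_configs <- list(NULL)
  structure(list(preprocess = preprocess, thresholds = thresholds,
                 family = family, eec_configs = eec_configs,
                 features = features, cv_folds = as.integer(cv_folds),
                 rule_version = rule_version, seed = as.integer(seed)),
            class = "grid_spec")
}

grid_configurations <- function(grid) {
  out <- list()
  for (h in seq_along(grid$eec_configs)) {
    for (pp in grid$preprocess) {
      for (th in grid$thresholds) {
        out[[length(out) + 1L]] <- list(preprocess = pp, threshold = th,
                                        family = grid$family, hyper = h)
      }
    }
  }
  out
}

config_label <- function(cfg, n_hyper) {
  lab <- paste0(cfg$family,
                if (cfg$preprocess != "none")
                  paste0("_", toupper(cfg$preprocess)) else "",
                " & ", cfg$threshold)
  if (n_hyper > 1) lab <- paste0(lab, " [h", cfg$hyper, "]")
  lab
}

fit_risk_model <- function(train, features, family, weights, hyper_config) {
  if (family == "EEC") {
    fit_easy_ensemble(train, features, weights = weights,
                      config = hyper_config)
  } else {
    fit_weighted_logistic(train, features, weights = weights)
  }
}

derive_threshold <- function(scores_train, y_train, kind, train,
                             rule_version) {
  curve <- roc_curve(scores_train, y_train)
  if (kind == "TY") {
    youden_threshold(curve)
  } else {
    rule <- uspstf_eligibility(train, version = rule_version)
    ref_spec <- sum(rule == 0 & y_train == 0) / sum(y_train == 0)
    specificity_matched_threshold(curve, ref_spec)
  }
}

#' Fit a complete eligibility mechanism on a training split
#'
#' Runs the pre-processing (reweighing), model fitting and threshold
#' derivation for one configuration on the full training data, freezing the
#' threshold for later testing.
#'
#' @param cohort training data.
#' @param preprocess `"none"`, `"rw1"` or `"rw2"`.
#' @param threshold `"TU"` or `"TY"`.
#' @param family `"EEC"` or `"LR"`.
#' @param features model feature columns.
#' @param config an [eec_config()] (EEC family only).
#' @param rule_version USPSTF rule year anchoring TU.
#' @return An object of class `eligibility_model`: `model`, frozen `policy`,
#'   `reweigh` result (or NULL) and the configuration.
#' @export
fit_eligibility_model <- function(cohort, preprocess = "rw1",
                                  threshold = "TU", family = "EEC",
                                  features = default_model_features(),
                                  config = eec_config(),
                                  rule_version = 2021) {
  attrs <- preprocess_attributes(preprocess)
  rw <- if (is.null(attrs)) NULL else reweigh(cohort, attrs)
  weights <- if (is.null(rw)) rep(1, nrow(cohort)) else rw$row_weights
  model <- fit_risk_model(cohort, features, family, weights, config)
  scores <- predict_risk(model, cohort)
  policy <- derive_threshold(scores, cohort$outcome, threshold, cohort,
                             rule_version)
  structure(list(model = model, policy = policy, reweigh = rw,
                 preprocess = preprocess, threshold = threshold,
                 family = family, features = features,
                 rule_version = rule_version),
            class = "eligibility_model")
}

#' Cross-validated grid search over fairness configurations
#'
#' For every configuration in the grid and every fold: reweighing weights
#' are fitted on the training folds, the risk model is fitted with those
#' weights, the threshold (TU or TY) is derived on the training folds, and
#' the held-out fold contributes an AUC and an EOD (race TPR gap at the
#' threshold). A fold whose held-out part lacks a race group's positives
#' contributes no EOD and is counted.
#'
#' Selection: the best-AUC configuration anchors a predictive-performance
#' floor; configurations are eligible when a paired across-fold t-test
#' against the anchor is non-significant (alpha = 0.05) or their mean AUC is
#' within the non-inferiority margin (0.01). Among eligible configurations
#' the one with the smallest |mean EOD| wins; ties break by grid order.
#'
#' @param cohort training data.
#' @param grid a [grid_spec()].
#' @param alpha significance level of the paired AUC comparison.
#' @param margin non-inferiority fallback margin on mean AUC.
#' @return An object of class `selection_result`: `chosen` (configuration),
#'   `audit` (one row per configuration), per-configuration `auc_series` /
#'   `eod_series` / `thresholds`, and `final` — the chosen configuration
#'   refitted on the full training data via [fit_eligibility_model()].
#' @export
run_grid_search <- function(cohort, grid, alpha = 0.05, margin = 0.01) {
  stopifnot(inherits(grid, "grid_spec"))
  configs <- grid_configurations(grid)
  folds <- stratified_kfold(cohort$outcome, grid$cv_folds, grid$seed)
  k <- grid$cv_folds
  n_cfg <- length(configs)
  auc_series <- matrix(NA_real_, k, n_cfg)
  eod_series <- matrix(NA_real_, k, n_cfg)
  thr_series <- matrix(NA_real_, k, n_cfg)

  # per-fold artifacts reusable across configurations
  for (f in seq_len(k)) {
    train <- cohort[folds != f, , drop = FALSE]
    heldout <- cohort[folds == f, , drop = FALSE]
    weights_by_pp <- lapply(stats::setNames(nm = grid$preprocess),
                            function(pp) {
      attrs <- preprocess_attributes(pp)
      if (is.null(attrs)) rep(1, nrow(train))
      else reweigh(train, attrs)$row_weights
    })
    model_cache <- new.env(parent = emptyenv())
    for (ci in seq_len(n_cfg)) {
      cfg <- configs[[ci]]
      mkey <- paste(cfg$preprocess, cfg$hyper)
      fit <- model_cache[[mkey]]
      if (is.null(fit)) {
        fit <- fit_risk_model(train, grid$features, grid$family,
                              weights_by_pp[[cfg$preprocess]],
                              grid$eec_configs[[cfg$hyper]])
        scores_train <- predict_risk(fit, train)
        scores_heldout <- predict_risk(fit, heldout)
        model_cache[[mkey]] <- list(fit = fit, scores_train = scores_train,
                                    scores_heldout = scores_heldout)
      }
      cached <- model_cache[[mkey]]
      policy <- derive_threshold(cached$scores_train, train$outcome,
                                 cfg$threshold, train, grid$rule_version)
      thr_series[f, ci] <- policy$value
      auc_series[f, ci] <- roc_auc(roc_curve(cached$scores_heldout,
                                             heldout$outcome))
      eligible <- apply_policy(cached$scores_heldout, policy)
      rates <- group_rates(eligible, heldout$outcome, heldout$race)
      eod_series[f, ci] <- tryCatch(eod(rates), error = function(e) NA_real_)
    }
  }

  mean_auc <- colMeans(auc_series)
  mean_eod <- colMeans(eod_series, na.rm = TRUE)
  best <- which.max(mean_auc)
  p_vs_best <- vapply(seq_len(n_cfg), function(ci) {
    d <- auc_series[, ci] - auc_series[, best]
    if (stats::sd(d) == 0) return(1)
    stats::t.test(d)$p.value
  }, numeric(1))
  eligible_cfg <- p_vs_best >= alpha | mean_auc >= mean_auc[best] - margin
  if (!any(eligible_cfg)) stop("all configurations excluded; see audit")
  cand <- which(eligible_cfg)
  chosen <- cand[which.min(abs(mean_eod[cand]))]

  labels <- vapply(configs, config_label, character(1),
                   n_hyper = length(grid$eec_configs))
  audit <- data.frame(configuration = labels,
                      preprocess = vapply(configs, `[[`, "", "preprocess"),
                      threshold = vapply(configs, `[[`, "", "threshold"),
                      mean_auc = mean_auc,
                      p_auc_vs_best = p_vs_best,
                      mean_eod = mean_eod,
                      abs_mean_eod = abs(mean_eod),
                      n_eod_folds = colSums(!is.na(eod_series)),
                      eligible = eligible_cfg,
                      selected = seq_len(n_cfg) == chosen,
                      reason = ifelse(eligible_cfg,
                                      "performance not significantly reduced",
                                      "mean AUC significantly below best"))

  final <- fit_eligibility_model(
    cohort,
    preprocess = configs[[chosen]]$preprocess,
    threshold = configs[[chosen]]$threshold,
    family = grid$family,
    features = grid$features,
    config = grid$eec_configs[[configs[[chosen]]$hyper]],
    rule_version = grid$rule_version)

  structure(list(chosen = configs[[chosen]],
                 chosen_label = labels[chosen],
                 audit = audit,
                 auc_series = auc_series, eod_series = eod_series,
                 thresholds = thr_series, folds = folds,
                 final = final, grid = grid),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Selected configuration:", x$chosen_label, "\n\n")
  print(x$audit[c("configuration", "mean_auc", "p_auc_vs_best", "mean_eod",
                  "eligible", "selected")], row.names = FALSE, digits = 4)
  invisible(x)
}

binary_metrics <- function(eligible, labels) {
  tp <- sum(eligible == 1 & labels == 1)
  fn <- sum(eligible == 0 & labels == 1)
  fp <- sum(eligible == 1 & labels == 0)
  tn <- sum(eligible == 0 & labels == 0)
  c(sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn))
}

# Stratified bootstrap draw of a fraction of each outcome stratum (with
# replacement, preserving relative class counts); frac = 1 means "the whole
# split, no resampling", so a single replicate at full fraction reproduces
# direct whole-split evaluation exactly.
draw_replicate <- function(strata_idx, frac) {
  if (frac >= 1) return(unlist(strata_idx, use.names = FALSE))
  unlist(lapply(strata_idx, function(ix)
    ix[sample.int(length(ix), max(1L, floor(frac * length(ix))),
                  replace = TRUE)]),
    use.names = FALSE)
}

replicate_metrics <- function(idx, scores, eligible, cohort) {
  y <- cohort$outcome[idx]
  race <- cohort$race[idx]
  s <- scores[idx]; e <- eligible[idx]
  rates <- group_rates(e, y, race)
  if (!all(rates$tpr_defined) || length(unique(y)) < 2) return(NULL)
  per_race_auc <- vapply(c("black", "white"), function(rr) {
    sel <- race == rr
    if (length(unique(y[sel])) < 2) return(NA_real_)
    roc_auc(roc_curve(s[sel], y[sel]))
  }, numeric(1))
  c(binary_metrics(e, y),
    auc = roc_auc(roc_curve(s, y)),
    auc_black = per_race_auc[["black"]],
    auc_white = per_race_auc[["white"]],
    tpr_black = rates$tpr[rates$group == "black"],
    tpr_white = rates$tpr[rates$group == "white"],
    eod = eod(rates))
}

#' Testing-phase evaluation of a frozen eligibility mechanism
#'
#' Evaluates a trained [fit_eligibility_model()] artifact on a disjoint test
#' split: `n_boot` stratified bootstrap resamples of `frac` of the split
#' (drawn with replacement within outcome strata; `frac = 1` evaluates the
#' whole split once, without resampling),
#' each contributing sensitivity, specificity, F1, overall and per-race AUC,
#' per-race TPRs and the EOD. The EOD series feeds a one-sample t-test,
#' Hedges' g_rm and the CL effect size on the paired race TPR series.
#' A replicate in which a race group has no positives is redrawn (counted).
#'
#' @param artifact an `eligibility_model`.
#' @param test_cohort test split, disjoint from training.
#' @param n_boot number of replicates.
#' @param frac fraction of each outcome stratum per replicate.
#' @param seed integer seed.
#' @param max_redraws cap on total replacement draws for invalid replicates.
#' @return An object of class `test_report`: `replicates` (one row each),
#'   `summary` (means and percentile 95% CIs), `eod_test`, `g_rm`, `cl`,
#'   the frozen `policy` and `n_redrawn`.
#' @export
run_test_phase <- function(artifact, test_cohort, n_boot = 500L, frac = 0.8,
                           seed = 1L, max_redraws = 1000L) {
  stopifnot(inherits(artifact, "eligibility_model"),
            frac > 0, frac <= 1, n_boot >= 1)
  scores <- predict_risk(artifact$model, test_cohort)
  eligible <- apply_policy(scores, artifact$policy)
  strata_idx <- split(seq_len(nrow(test_cohort)), test_cohort$outcome)
  rows <- vector("list", n_boot)
  n_redrawn <- 0L
  with_local_seed(substream(seed, 271L), {
    for (r in seq_len(n_boot)) {
      repeat {
        idx <- draw_replicate(strata_idx, frac)
        met <- replicate_metrics(idx, scores, eligible, test_cohort)
        if (!is.null(met)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraws) {
          stop("too many invalid replicates (a race group keeps losing ",
               "all its positives); increase frac or the test split size")
        }
      }
      rows[[r]] <- met
    }
  })
  replicates <- as.data.frame(do.call(rbind, rows))
  summarize <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), lo = unname(stats::quantile(v, 0.025, type = 7)),
      hi = unname(stats::quantile(v, 0.975, type = 7)))
  }
  summary <- t(vapply(replicates, summarize, numeric(3)))
  eod_test <- if (n_boot >= 2) eod_ttest(replicates$eod) else NULL
  g_rm <- if (n_boot >= 3) hedges_g_rm(replicates$tpr_black,
                                       replicates$tpr_white) else NA_real_
  cl <- if (n_boot >= 2) cl_effect_size(replicates$tpr_black,
                                        replicates$tpr_white) else NA_real_
  structure(list(replicates = replicates, summary = summary,
                 eod_test = eod_test, g_rm = g_rm, cl = cl,
                 policy = artifact$policy, scores = scores,
                 eligible = eligible, n_boot = n_boot, frac = frac,
                 n_redrawn = n_redrawn),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("Test phase: %d replicates at %.0f%% of the split (policy %s = %.5g)\n",
              x$n_boot, 100 * x$frac, x$policy$kind, x$policy$value))
  print(round(x$summary, 4))
  if (!is.null(x$eod_test)) {
    cat(sprintf("EOD: mean %.4f, t p = %.4g, Hedges g_rm = %.3g, CL = %.3g\n",
                x$eod_test$mean, x$eod_test$p, x$g_rm, x$cl))
  }
  invisible(x)
}

#' Compare eligibility policies on a common test split
#'
#' Evaluates rule-based and risk-based policies on identical stratified
#' resamples (so per-replicate series are paired across policies) and
#' reports one row per policy: sensitivity, specificity, F1, AUC (risk-based
#' policies only; rule-based policies have binary outputs and get `NA`),
#' average EOD with percentile CI, the EOD t-test p-value and the paired
#' effect sizes. Against a designated reference policy it also runs
#' McNemar's test on the full split, and DeLong's test for risk-risk pairs.
#'
#' @param test_cohort the test split.
#' @param policies named list; each element is either
#'   `list(kind = "rule", version = 2013 or 2021)` or
#'   `list(kind = "risk", artifact = <eligibility_model>)`.
#' @param n_boot,frac,seed replicate settings as in [run_test_phase()].
#' @param reference name of the policy all others are tested against
#'   (default: the first).
#' @return An object of class `policy_comparison`: `table`, `tests`
#'   (per-policy McNemar/DeLong vs reference), `replicates`.
#' @export
compare_policies <- function(test_cohort, policies, n_boot = 500L,
                             frac = 0.8, seed = 1L,
                             reference = names(policies)[1]) {
  if (length(policies) < 2) stop("need at least 2 policies to compare")
  if (is.null(names(policies)) || any(names(policies) == "")) {
    stop("policies must be a named list")
  }
  y <- test_cohort$outcome
  race <- test_cohort$race
  evaluated <- lapply(policies, function(p) {
    if (p$kind == "rule") {
      list(scores = NULL,
           eligible = uspstf_eligibility(test_cohort, version = p$version))
    } else if (p$kind == "risk") {
      s <- predict_risk(p$artifact$model, test_cohort)
      list(scores = s, eligible = apply_policy(s, p$artifact$policy))
    } else stop("policy kind must be 'rule' or 'risk'")
  })
  strata_idx <- split(seq_len(nrow(test_cohort)), y)
  reps <- lapply(policies, function(p) vector("list", n_boot))
  with_local_seed(substream(seed, 557L), {
    for (r in seq_len(n_boot)) {
      idx <- draw_replicate(strata_idx, frac)
      for (nm in names(policies)) {
        ev <- evaluated[[nm]]
        yi <- y[idx]; ri <- race[idx]; ei <- ev$eligible[idx]
        rates <- group_rates(ei, yi, ri)
        eod_r <- tryCatch(eod(rates), error = function(e) NA_real_)
        auc_r <- if (is.null(ev$scores) || length(unique(yi)) < 2) NA_real_
                 else roc_auc(roc_curve(ev$scores[idx], yi))
        reps[[nm]][[r]] <- c(binary_metrics(ei, yi), auc = auc_r,
                             tpr_black = rates$tpr[rates$group == "black"],
                             tpr_white = rates$tpr[rates$group == "white"],
                             eod = eod_r)
      }
    }
  })
  reps <- lapply(reps, function(l) as.data.frame(do.call(rbind, l)))
  table <- do.call(rbind, lapply(names(policies), function(nm) {
    d <- reps[[nm]]
    eodv <- d$eod[!is.na(d$eod)]
    tt <- if (length(eodv) >= 2) eod_ttest(eodv) else NULL
    ok <- !is.na(d$eod)
    data.frame(policy = nm,
               sensitivity = mean(d$sensitivity),
               specificity = mean(d$specificity),
               f1 = mean(d$f1, na.rm = TRUE),
               auc = mean(d$auc),
               avg_eod = mean(eodv),
               eod_lo = if (!is.null(tt)) tt$ci[1] else NA_real_,
               eod_hi = if (!is.null(tt)) tt$ci[2] else NA_real_,
               eod_p = if (!is.null(tt)) tt$p else NA_real_,
               g_rm = if (sum(ok) >= 3)
                 hedges_g_rm(d$tpr_black[ok], d$tpr_white[ok]) else NA_real_,
               cl = if (sum(ok) >= 2)
                 cl_effect_size(d$tpr_black[ok], d$tpr_white[ok])
                 else NA_real_)
  }))
  ref_ev <- evaluated[[reference]]
  tests <- lapply(setdiff(names(policies), reference), function(nm) {
    ev <- evaluated[[nm]]
    out <- list(policy = nm,
                mcnemar = mcnemar_test(ev$eligible == y, ref_ev$eligible == y))
    if (!is.null(ev$scores) && !is.null(ref_ev$scores)) {
      out$delong <- delong_test(ev$scores, ref_ev$scores, y)
    }
    out
  })
  names(tests) <- setdiff(names(policies), reference)
  structure(list(table = table, tests = tests, replicates = reps,
                 reference = reference),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nPaired tests vs reference '", x$reference, "':\n", sep = "")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %s: McNemar p = %.4g%s\n", nm, t$mcnemar$p,
                if (!is.null(t$delong))
                  sprintf(", DeLong p = %.4g", t$delong$p) else ""))
  }
  invisible(x)
}
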