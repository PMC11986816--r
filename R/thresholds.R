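# Post-processing eligibility thresholds --------------------------------------
#
# Risk scores become screening-eligibility calls through a single global
# decision convention: eligible iff score >= threshold. Two data-driven
# thresholds are provided: TY at the ROC Youden index (max TPR - FPR) and TU
# matched to the specificity of a rule-based comparator (at-least semantics:
# the most sensitive cut-point whose specificity is not below the
# reference), plus the rule-based USPSTF 2013/2021 criteria themselves.

#' Empirical ROC curve
#'
#' Exact empirical ROC over all distinct score cut-points under the decision
#' rule "eligible iff score >= threshold". A sentinel `Inf` row gives the
#' (FPR 0, TPR 0) endpoint; the minimum score gives (1, 1).
#'
#' @param scores finite numeric risk scores.
#' @param labels binary outcome labels (0/1), both classes present.
#' @return An object of class `roc_points`: data.frame with `threshold`,
#'   `tpr`, `fpr`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both outcome classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct cut-point (>= semantics)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1)[last_of_tie]
  fp <- cumsum(y == 0)[last_of_tie]
  thr <- s[last_of_tie]
  curve <- data.frame(threshold = c(Inf, thr),
                      tpr = c(0, tp / n_pos),
                      fpr = c(0, fp / n_neg))
  curve$specificity <- 1 - curve$fpr
  structure(curve, class = c("roc_points", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the empirical ROC, which equals the all-pairs
#' concordance probability (ties counted 1/2) exactly.
#'
#' @param curve a `roc_points` object from [roc_curve()].
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_points"))
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
}

#' Construct a threshold policy
#'
#' @param kind one of `"TY"` (Youden), `"TU"` (specificity-matched) or
#'   `"fixed"`.
#' @param value risk threshold in [0, 1].
#' @param reference_specificity for TU policies, the specificity that was
#'   matched.
#' @param attained `FALSE` flags a TU policy whose reference specificity was
#'   unreachable (the maximum cut-point was returned instead).
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(kind = c("fixed", "TY", "TU"), value,
                             reference_specificity = NULL, attained = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(value), length(value) == 1, value >= 0, value <= 1)
  structure(list(kind = kind, value = value,
                 reference_specificity = reference_specificity,
                 attained = attained),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("<threshold_policy %s = %.6g%s%s>\n", x$kind, x$value,
              if (!is.null(x$reference_specificity))
                sprintf(" (ref specificity %.4g)", x$reference_specificity)
              else "",
              if (!x$attained) " [reference not attained]" else ""))
  invisible(x)
}

finite_cutpoints <- function(curve) curve[is.finite(curve$threshold), ]

#' Youden-index threshold (TY)
#'
#' The cut-point maximizing J = TPR - FPR, i.e. equal weight on sensitivity
#' and specificity. Ties are broken toward the smaller threshold, which
#' favors sensitivity — the natural tilt for screening eligibility.
#'
#' @param curve a `roc_points` object.
#' @return A `threshold_policy` of kind `"TY"`.
#' @export
youden_threshold <- function(curve) {
  pts <- finite_cutpoints(curve)
  j <- pts$tpr - pts$fpr
  best <- which(j >= max(j) - 1e-15)
  value <- min(pts$threshold[best])
  threshold_policy("TY", min(max(value, 0), 1))
}

#' Specificity-matched threshold (TU)
#'
#' The smallest (most sensitive) cut-point whose specificity is at least
#' `reference_specificity` — typically the empirical specificity of a
#' rule-based eligibility comparator, so that gains relative to the rule
#' come entirely from sensitivity. If no cut-point attains the reference,
#' the maximum cut-point is returned with `attained = FALSE`.
#'
#' @param curve a `roc_points` object.
#' @param reference_specificity target specificity in [0, 1).
#' @return A `threshold_policy` of kind `"TU"`.
#' @export
specificity_matched_threshold <- function(curve, reference_specificity) {
  stopifnot(reference_specificity >= 0, reference_specificity < 1)
  pts <- finite_cutpoints(curve)
  ok <- pts$specificity >= reference_specificity
  if (!any(ok)) {
    warning("reference specificity ", reference_specificity,
            " unattainable; returning the maximum cut-point")
    return(threshold_policy("TU", min(max(pts$threshold), 1),
                            reference_specificity, attained = FALSE))
  }
  value <- min(pts$threshold[ok])
  threshold_policy("TU", min(max(value, 0), 1), reference_specificity)
}

#' Rule-based USPSTF screening eligibility
#'
#' The 2013 criteria: age 55-80, at least 30 pack-years, and currently
#' smoking or quit within the past 15 years. The 2021 revision lowers the
#' age floor to 50 and the pack-year minimum to 20.
#'
#' @param rows data.frame with `age`, `pack_years`, `smoking_status`,
#'   `years_since_quit`.
#' @param version `2013` or `2021`.
#' @return Integer 0/1 eligibility vector.
#' @export
uspstf_eligibility <- function(rows, version = 2021) {
  needed <- c("age", "pack_years", "smoking_status", "years_since_quit")
  missing <- setdiff(needed, names(rows))
  if (length(missing)) {
    stop("rows lack required fields: ", paste(missing, collapse = ", "))
  }
  if (anyNA(rows[needed])) stop("missing values in eligibility fields")
  version <- as.integer(version)
  if (!version %in% c(2013L, 2021L)) stop("version must be 2013 or 2021")
  age_min <- if (version == 2021L) 50 else 55
  py_min <- if (version == 2021L) 20 else 30
  recency <- rows$smoking_status == "current" | rows$years_since_quit <= 15
  as.integer(rows$age >= age_min & rows$age <= 80 &
               rows$pack_years >= py_min & recency)
}

#' Apply a threshold policy to risk scores
#'
#' @param scores numeric risk scores in [0, 1].
#' @param policy a `threshold_policy`.
#' @return Integer 0/1 eligibility vector (eligible iff score >= value).
#' @export
apply_policy <- function(scores, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  as.integer(scores >= policy$value)
}
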