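# Fixture builders and independent brute-force oracles used across tests.

# A toy cohort with given per-(group, outcome) counts; columns race/gender
# are optional extras.
counts_cohort <- function(counts, attr = "race") {
  # counts: data.frame with columns level, outcome, n
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(level = rep(counts$level[i], counts$n[i]),
               outcome = rep(counts$outcome[i], counts$n[i]))
  }))
  names(rows)[1] <- attr
  rows
}

# Random small cohort with race, gender and outcome; regenerated until all
# (race x gender, outcome) cells are occupied.
random_toy_cohort <- function(n = 2000) {
  repeat {
    co <- data.frame(
      race = sample(c("black", "white"), n, TRUE, prob = c(0.3, 0.7)),
      gender = sample(c("female", "male"), n, TRUE),
      outcome = rbinom(n, 1, 0.3))
    key <- table(paste(co$race, co$gender, co$outcome))
    if (length(key) == 8) return(co)
  }
}

# All-pairs concordance probability (ties counted 1/2): the rank-free AUC
# oracle.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force threshold search over all distinct cut-points under the
# "eligible iff score >= t" rule.
brute_force_thresholds <- function(scores, labels, ref_spec = NULL) {
  cuts <- sort(unique(scores))
  tpr <- vapply(cuts, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(scores[labels == 0] >= t), numeric(1))
  j <- tpr - fpr
  ty <- min(cuts[j >= max(j) - 1e-15])
  tu <- NULL
  if (!is.null(ref_spec)) {
    ok <- (1 - fpr) >= ref_spec
    tu <- if (any(ok)) min(cuts[ok]) else max(cuts)
  }
  list(ty = ty, tu = tu)
}

# Leave-one-out jackknife variance of an AUC difference.
jackknife_auc_diff_var <- function(scores_a, scores_b, labels) {
  n <- length(labels)
  theta <- vapply(seq_len(n), function(i) {
    concordance_auc(scores_a[-i], labels[-i]) -
      concordance_auc(scores_b[-i], labels[-i])
  }, numeric(1))
  (n - 1) / n * sum((theta - mean(theta))^2)
}

# Random score/label instance with injected ties.
random_roc_instance <- function(n) {
  scores <- round(runif(n), sample(1:2, 1))
  labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
  if (length(unique(labels)) < 2) {
    labels[1] <- 0L; labels[2] <- 1L
  }
  list(scores = scores, labels = labels)
}
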