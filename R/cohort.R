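# Synthetic cohort generation -------------------------------------------------
#
# Seeded generator for cohorts that mimic the structure of a large lung
# screening trial population: heavy outcome imbalance (~4% lung cancer
# incidence), a small minority-race share (~6%), near-equal group base rates,
# and the feature schema used by risk-based eligibility models (demographics,
# smoking history, lung-related conditions).

#' Bias-injection specification for the cohort simulator
#'
#' Describes the mechanisms through which group-dependent bias enters the
#' generated data. All mechanisms act on the minority (black) group and are
#' off by default, so an unconfigured simulation has no structural unfairness
#' beyond the configured base rates.
#'
#' @param feature_shift named numeric vector; each element is added to the
#'   named feature column for minority rows (e.g. `c(pack_years = -8)` makes
#'   minority smoking exposure look lighter than it is).
#' @param group_intercept log-odds added to the minority group's outcome
#'   model on top of its calibrated base-rate intercept.
#' @param label_noise length-2 numeric `c(minority, majority)`: probability
#'   that a true positive outcome is recorded as negative in each group
#'   (differential under-ascertainment).
#' @return An object of class `bias_spec`.
#' @export
bias_spec <- function(feature_shift = NULL,
                      group_intercept = 0,
                      label_noise = c(minority = 0, majority = 0)) {
  stopifnot(is.numeric(group_intercept), length(group_intercept) == 1)
  if (!is.null(feature_shift)) {
    stopifnot(is.numeric(feature_shift), !is.null(names(feature_shift)))
  }
  label_noise <- rep_len(as.numeric(label_noise), 2L)
  if (any(label_noise < 0 | label_noise > 1)) {
    stop("label_noise probabilities must lie in [0, 1]")
  }
  structure(list(feature_shift = feature_shift,
                 group_intercept = group_intercept,
                 label_noise = c(minority = label_noise[1],
                                 majority = label_noise[2])),
            class = "bias_spec")
}

#' Is any bias mechanism active?
#' @param bias a [bias_spec()] object.
#' @return `TRUE` if any mechanism is non-trivial.
#' @keywords internal
bias_is_active <- function(bias) {
  !is.null(bias$feature_shift) && any(bias$feature_shift != 0) ||
    bias$group_intercept != 0 || any(bias$label_noise != 0)
}

#' Default generating-model coefficients
#'
#' Log-odds coefficients of the synthetic outcome model. Features enter on a
#' fixed standardized scale (see the generator internals); the overall
#' magnitude was chosen once so that the true linear predictor discriminates
#' cases from non-cases with AUC close to 0.80, the working point of
#' published lung cancer risk models.
#' @return Named numeric vector.
#' @export
default_risk_coefficients <- function() {
  c(age             =  0.44,
    education_level = -0.13,
    bmi             = -0.13,
    smoking_current =  0.40,
    pack_years      =  0.44,
    years_smoked    =  0.26,
    years_since_quit = -0.26,
    copd            =  0.40,
    personal_health_history = 0.31)
}

#' Simulation configuration for a synthetic screening cohort
#'
#' @param n cohort size (rows).
#' @param target_prevalence marginal outcome (lung cancer) probability.
#' @param minority_share probability that a participant is in the minority
#'   (black) race group.
#' @param base_rate_minority,base_rate_majority outcome probability within
#'   each race group. The defaults are mutually consistent with
#'   `target_prevalence` (share-weighted average 0.0412); when they are not,
#'   the group base rates govern generation.
#' @param risk_coefficients named log-odds coefficients of the generating
#'   logistic model (see [default_risk_coefficients()]).
#' @param bias a [bias_spec()].
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n,
                       target_prevalence = 0.0412,
                       minority_share = 0.0574,
                       base_rate_minority = 0.0444,
                       base_rate_majority = 0.0410,
                       risk_coefficients = default_risk_coefficients(),
                       bias = bias_spec(),
                       seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be an integer >= 1")
  probs <- c(target_prevalence, minority_share,
             base_rate_minority, base_rate_majority)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(is.numeric(risk_coefficients), !is.null(names(risk_coefficients)))
  if (!inherits(bias, "bias_spec")) stop("bias must be a bias_spec()")
  structure(list(n = n,
                 target_prevalence = target_prevalence,
                 minority_share = minority_share,
                 base_rate_minority = base_rate_minority,
                 base_rate_majority = base_rate_majority,
                 risk_coefficients = risk_coefficients,
                 bias = bias,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Derived per-operation seeds: one global seed governs all randomness, split
# into fixed substreams so that e.g. calibration and cohort drawing never
# share a stream.
substream <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

# Draw the raw feature block (no outcome, no bias applied). Vectorized;
# assumes the RNG state has been set by the caller.
draw_features <- function(n) {
  # enrollment-age window of the emulated trial
  lo <- pnorm(55, 62, 6); hi <- pnorm(74, 62, 6)
  age <- qnorm(runif(n, lo, hi), 62, 6)
  education_level <- sample.int(7L, n, replace = TRUE,
                                prob = c(.04, .18, .22, .14, .22, .12, .08))
  bmi <- pmin(pmax(rnorm(n, 27.3, 4.8), 15), 55)
  current <- runif(n) < 0.38
  start_age <- pmin(pmax(round(rnorm(n, 18, 3)), 10), 35)
  max_quit <- pmax(floor(age - start_age) - 1, 0)
  years_since_quit <- ifelse(current, 0,
                             pmin(round(rgamma(n, shape = 1.4, scale = 13)),
                                  max_quit))
  years_smoked <- pmax(floor(age) - start_age - years_since_quit, 1)
  packs_per_day <- pmin(pmax(rgamma(n, shape = 1.8, scale = 0.55), 0.05), 4)
  pack_years <- packs_per_day * years_smoked
  bronchitis <- runif(n) < 0.12
  emphysema <- runif(n) < 0.08
  fam_history <- runif(n) < 0.09
  prior_cancer <- runif(n) < 0.06
  xray_history <- runif(n) < 0.40
  data.frame(
    age = age,
    education_level = education_level,
    bmi = bmi,
    smoking_status = factor(ifelse(current, "current", "former"),
                            levels = c("current", "former")),
    pack_years = pack_years,
    years_smoked = years_smoked,
    years_since_quit = years_since_quit,
    copd = as.integer(bronchitis | emphysema),
    personal_health_history = as.integer(fam_history | prior_cancer |
                                           xray_history)
  )
}

# Linear predictor of the generating model (no intercept). Features are
# centered and scaled by fixed constants, not empirical moments, so a row's
# contribution does not depend on the rest of the cohort.
lp_features <- function(features, coefficients) {
  std <- cbind(
    age              = (features$age - 62) / 6,
    education_level  = (features$education_level - 4) / 1.8,
    bmi              = (features$bmi - 27.3) / 4.8,
    smoking_current  = as.numeric(features$smoking_status == "current"),
    pack_years       = (features$pack_years - 28) / 22,
    years_smoked     = (features$years_smoked - 34) / 12,
    years_since_quit = features$years_since_quit / 14,
    copd             = features$copd,
    personal_health_history = features$personal_health_history
  )
  beta <- numeric(ncol(std))
  names(beta) <- colnames(std)
  known <- intersect(names(coefficients), names(beta))
  unknown <- setdiff(names(coefficients), names(beta))
  if (length(unknown)) {
    stop("unknown risk_coefficients: ", paste(unknown, collapse = ", "))
  }
  beta[known] <- coefficients[known]
  drop(std %*% beta)
}

# Cache of calibrated intercepts keyed by the configuration slots they
# depend on; calibration is Monte-Carlo and would otherwise dominate repeated
# small-cohort generation.
.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate the logistic intercept of the generating model
#'
#' Finds the intercept `b0` such that the marginal outcome probability of the
#' generating logistic model equals `target` within `tol`, by monotone
#' bisection over a Monte-Carlo sample of the feature linear predictor.
#'
#' @param config a [sim_config()].
#' @param target the marginal probability to match; defaults to
#'   `config$target_prevalence`.
#' @param n_mc Monte-Carlo sample size for the feature draw.
#' @param tol absolute tolerance on the recovered marginal probability.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config, target = config$target_prevalence,
                                n_mc = 100000L, tol = 1e-3) {
  stopifnot(inherits(config, "sim_config"))
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  key <- paste(format(c(config$risk_coefficients, target, n_mc), digits = 15),
               collapse = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  lp <- with_local_seed(substream(config$seed, 104729L), {
    # calibration uses its own substream so cohort draws are unaffected
    lp_features(draw_features(n_mc), config$risk_coefficients)
  })
  f <- function(b0) mean(plogis(b0 + lp)) - target
  lo <- -30; hi <- 10
  if (f(lo) > 0 || f(hi) < 0) {
    stop("calibration failure: target prevalence ", target,
         " not bracketed by intercepts in [-30, 10]")
  }
  b0 <- (lo + hi) / 2
  for (i in 1:60) {
    b0 <- (lo + hi) / 2
    fb <- f(b0)
    if (abs(fb) < tol / 4) break
    if (fb < 0) lo <- b0 else hi <- b0
  }
  if (abs(f(b0)) > tol) {
    stop("calibration failure: bisection did not reach tolerance ", tol)
  }
  .calibration_cache[[key]] <- b0
  b0
}

# Evaluate a block with a temporary RNG state, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic screening cohort
#'
#' Draws `config$n` participants with the schema used throughout the package:
#' demographics (`age`, `education_level`, `bmi`), smoking history
#' (`smoking_status`, `pack_years`, `years_smoked`, `years_since_quit`),
#' aggregated lung-related flags (`copd` = bronchitis or emphysema,
#' `personal_health_history` = family history, prior cancer or chest X-ray
#' history), sensitive attributes (`race`, `gender`) and a binary `outcome`
#' drawn from a logistic model with group-calibrated intercepts. Bias
#' mechanisms from the configuration are applied to the minority group.
#'
#' The true (pre-noise) linear predictor is attached as attribute
#' `"linear_predictor"` so downstream tests can compare a fitted model
#' against the generating model's oracle discrimination.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with class `cohort`; the configuration is attached
#'   as attribute `"config"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  b0_major <- calibrate_intercept(config, target = config$base_rate_majority)
  b0_minor <- calibrate_intercept(config, target = config$base_rate_minority)
  with_local_seed(substream(config$seed, 1L), {
    n <- config$n
    features <- draw_features(n)
    race <- factor(ifelse(runif(n) < config$minority_share, "black", "white"),
                   levels = c("black", "white"))
    gender <- factor(ifelse(runif(n) < 0.41, "female", "male"),
                     levels = c("female", "male"))
    bias <- config$bias
    minority <- race == "black"
    # outcome is drawn from the *true* features; feature_shift below distorts
    # only the recorded values, emulating measurement bias
    lp <- lp_features(features, config$risk_coefficients) +
      ifelse(minority, b0_minor + bias$group_intercept, b0_major)
    outcome <- as.integer(runif(n) < plogis(lp))
    if (any(bias$label_noise > 0)) {
      flip_p <- ifelse(minority, bias$label_noise["minority"],
                       bias$label_noise["majority"])
      flip <- outcome == 1L & runif(n) < flip_p
      outcome[flip] <- 0L
    }
    if (!is.null(bias$feature_shift)) {
      for (feat in names(bias$feature_shift)) {
        if (!feat %in% names(features)) {
          stop("feature_shift names unknown feature: ", feat)
        }
        features[[feat]][minority] <-
          features[[feat]][minority] + bias$feature_shift[[feat]]
        if (feat %in% c("pack_years", "years_smoked", "years_since_quit")) {
          features[[feat]] <- pmax(features[[feat]], 0)
        }
      }
    }
    cohort <- cbind(features, race = race, gender = gender, outcome = outcome)
    attr(cohort, "config") <- config
    attr(cohort, "linear_predictor") <- lp
    class(cohort) <- c("cohort", "data.frame")
    cohort
  })
}

#' Pooled two-proportion z-test on group outcome rates
#'
#' Tests equality of the outcome rate across the two levels of a grouping
#' attribute using the pooled-variance two-proportion z statistic (no
#' continuity correction), the check used to verify that group base rates
#' are statistically indistinguishable.
#'
#' @param cohort a cohort `data.frame` with an `outcome` column.
#' @param group_attr name of a column with exactly two observed levels.
#' @return A list with elements `z`, `p` (two-sided), and per-group counts.
#' @export
base_rate_ztest <- function(cohort, group_attr = "race") {
  g <- droplevels(factor(cohort[[group_attr]]))
  if (nlevels(g) != 2) {
    stop("group attribute '", group_attr, "' must have exactly 2 observed ",
         "levels, found ", nlevels(g))
  }
  y <- cohort$outcome
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  x1 <- sum(y[g == levels(g)[1]]); x2 <- sum(y[g == levels(g)[2]])
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)),
       rates = stats::setNames(c(p1, p2), levels(g)),
       counts = stats::setNames(c(x1, x2), levels(g)),
       n = stats::setNames(c(n1, n2), levels(g)))
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' The sidecar records the simulation configuration and seed so the cohort
#' can be regenerated exactly.
#'
#' @param cohort a `cohort` object.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  config <- attr(cohort, "config")
  if (!is.null(config)) {
    side <- unclass(config)
    side$bias <- unclass(side$bias)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path CSV path.
#' @return A `cohort` data.frame (without the generator attributes).
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort$smoking_status <- factor(cohort$smoking_status,
                                  levels = c("current", "former"))
  cohort$race <- factor(cohort$race, levels = c("black", "white"))
  cohort$gender <- factor(cohort$gender, levels = c("female", "male"))
  class(cohort) <- c("cohort", "data.frame")
  cohort
}
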