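#' Fit a binary-outcome logistic model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (the engine is [stats::glm()] with a binomial family), returning
#' the estimates together with their standard errors, the observed-information
#' covariance matrix and honest convergence diagnostics. (Quasi-)complete
#' separation is detected — diverging coefficients together with fitted
#' probabilities pinned at 0/1 — and raised as an error rather than returned
#' as a spuriously "converged" fit.
#'
#' @param design A data frame or matrix of named covariates (may have zero
#'   columns for an intercept-only model). Constant columns are an error.
#' @param outcome Binary vector (logical or 0/1) with both classes present.
#'   For trauma-score derivation the package convention is to model
#'   *survival*, so that higher GCS/SBP/SpO2 coefficients are positive and
#'   `ps()` is a survival probability.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `logistic_fit`: list with `coefficients`
#'   (including `(Intercept)`), `se`, `vcov`, `converged`, `n_iter`,
#'   `log_likelihood`, `n`, `fitted` and `linear_predictor`.
#' @examples
#' x <- rnorm(200); y <- rbinom(200, 1, plogis(x))
#' fit_logistic(data.frame(x = x), y)
#' @export
fit_logistic <- function(design, outcome, max_iter = 25) {
  outcome <- as.integer(outcome)
  stopifnot(all(outcome %in% 0:1))
  if (length(unique(outcome)) < 2)
    stop("outcome has a single class; cannot fit")
  if (is.null(design)) design <- data.frame(row.names = seq_along(outcome))
  design <- as.data.frame(design)
  if (ncol(design) > 0) {
    if (nrow(design) != length(outcome)) stop("design/outcome length mismatch")
    const <- vapply(design, function(x) length(unique(x)) == 1, logical(1))
    if (any(const))
      stop("constant covariate column(s): ", paste(names(design)[const], collapse = ", "))
  }
  dat <- cbind(design, .y = outcome)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter)),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- stats::coef(fit)
  pinned <- fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10
  if (any(abs(beta) > 15) && any(pinned))
    stop("perfect or quasi-complete separation detected; coefficients diverge",
         call. = FALSE)
  vc <- stats::vcov(fit)
  structure(list(
    coefficients = beta,
    se = sqrt(diag(vc)),
    vcov = vc,
    converged = fit$converged,
    n_iter = fit$iter,
    log_likelihood = as.numeric(stats::logLik(fit)),
    n = length(outcome),
    fitted = as.numeric(fit$fitted.values),
    linear_predictor = as.numeric(fit$linear.predictors)
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.2f, %sconverged in %d iter)\n",
              x$n, x$log_likelihood, if (x$converged) "" else "NOT ", x$n_iter))
  z <- x$coefficients / x$se
  print(data.frame(estimate = round(x$coefficients, 4), se = round(x$se, 4),
                   z = round(z, 2), p = signif(2 * stats::pnorm(-abs(z)), 3)))
  invisible(x)
}

#' Odds ratios from single-covariate logistic regression
#'
#' For a continuous covariate, the per-unit odds ratio `exp(beta)` with its
#' Wald 95% confidence interval and p-value. For a categorical covariate
#' (factor/character, or when `reference` is given), one odds ratio per
#' non-reference level against the reference — the form used to contrast
#' coded vital values against the normal (code 4) group.
#'
#' @param x Covariate vector.
#' @param outcome Binary outcome vector (package convention: survival).
#' @param reference Reference level for categorical mode; default the first
#'   factor level.
#' @param conf_level Confidence level for the Wald interval.
#' @return A data frame of class `odds_ratio` with columns `term`, `or`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
univariate_or <- function(x, outcome, reference = NULL, conf_level = 0.95) {
  categorical <- is.factor(x) || is.character(x) || !is.null(reference)
  if (categorical) {
    x <- factor(x)
    if (!is.null(reference)) {
      if (!reference %in% levels(x)) stop("reference level not present in x")
      x <- stats::relevel(x, ref = as.character(reference))
    }
    if (any(table(x) == 0)) stop("empty level in x")
    fit <- fit_logistic(data.frame(x = x), outcome)
    keep <- grep("^x", names(fit$coefficients))
    term <- sub("^x", "", names(fit$coefficients)[keep])
  } else {
    fit <- fit_logistic(data.frame(x = x), outcome)
    keep <- which(names(fit$coefficients) == "x")
    term <- "per_unit"
  }
  b <- fit$coefficients[keep]; s <- fit$se[keep]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = term, or = exp(b), ci_low = exp(b - zq * s),
                    ci_high = exp(b + zq * s),
                    p = 2 * stats::pnorm(-abs(b / s)), row.names = NULL)
  class(out) <- c("odds_ratio", "data.frame")
  out
}

.split_classes <- function(outcome) {
  outcome <- as.logical(outcome)
  if (anyNA(outcome)) stop("outcome contains NA")
  if (!any(outcome) || all(outcome)) stop("both outcome classes must be present")
  outcome
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen event case ranks above a randomly
#' chosen non-case, with ties counted one half (midrank convention) — i.e.
#' the Mann-Whitney U statistic divided by `n1 * n0`. Invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores Numeric score vector (higher = more likely an event).
#' @param outcome Binary event indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, outcome) {
  outcome <- .split_classes(outcome)
  if (length(scores) != length(outcome)) stop("length mismatch")
  if (anyNA(scores)) stop("scores contain NA")
  n1 <- sum(outcome); n0 <- sum(!outcome)
  r <- rank(scores)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.placements <- function(scores, outcome) {
  # midrank placement values: V10 per case, V01 per control
  n1 <- sum(outcome); n0 <- sum(!outcome)
  r_all <- rank(scores)
  v10 <- (r_all[outcome] - rank(scores[outcome])) / n0
  v01 <- 1 - (r_all[!outcome] - rank(scores[!outcome])) / n1
  list(v10 = v10, v01 = v01)
}

#' Compare two correlated ROC areas (DeLong's test)
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' subjects, using the placement-value (structural components) estimate of
#' the variance of the AUC difference, a two-sided z-test and a Wald 95%
#' confidence interval for the difference.
#'
#' @param scores_a,scores_b Paired numeric score vectors on the same
#'   subjects (higher = more likely an event).
#' @param outcome Binary event indicator.
#' @param conf_level Confidence level for the interval on the difference.
#' @return An object of class `roc_comparison`: `auc_a`, `auc_b`,
#'   `difference` (`auc_a - auc_b`), `z`, `p` (two-sided), `ci_low`,
#'   `ci_high`, `var_difference`.
#' @export
delong_compare <- function(scores_a, scores_b, outcome, conf_level = 0.95) {
  outcome <- .split_classes(outcome)
  if (length(scores_a) != length(outcome) || length(scores_b) != length(outcome))
    stop("length mismatch between scores and outcome")
  n1 <- sum(outcome); n0 <- sum(!outcome)
  pa <- .placements(scores_a, outcome); pb <- .placements(scores_b, outcome)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  diff <- auc_a - auc_b
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zq * sqrt(max(var_diff, 0))
  structure(list(auc_a = auc_a, auc_b = auc_b, difference = diff, z = z, p = p,
                 ci_low = diff - half, ci_high = diff + half,
                 var_difference = var_diff),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("DeLong AUC comparison: %.4f vs %.4f\n", x$auc_a, x$auc_b))
  cat(sprintf("  difference %.4f (95%% CI %.4f to %.4f), z = %.3f, p = %.4g\n",
              x$difference, x$ci_low, x$ci_high, x$z, x$p))
  invisible(x)
}

#' Hosmer-Lemeshow calibration statistic
#'
#' Groups subjects into equal-count bins of predicted risk (ties kept in one
#' group), then sums `(O - E)^2 / (n * pbar * (1 - pbar))` over groups, where
#' `O` and `E` are observed and expected event counts and `pbar` the mean
#' prediction in the group. Degrees of freedom are `g - 2` (the classical
#' statistic for a fitted model).
#'
#' @param predicted Predicted event probabilities in (0, 1).
#' @param outcome Binary event indicator.
#' @param n_groups Requested number of groups (default 10, deciles of risk);
#'   heavy ties can merge groups.
#' @return An object of class `calibration_result`: `n_groups` (actual),
#'   `observed`, `expected`, `group_n`, `chi2`, `df`, `p`.
#' @export
hosmer_lemeshow <- function(predicted, outcome, n_groups = 10) {
  outcome <- .split_classes(outcome)
  stopifnot(n_groups >= 2, length(predicted) == length(outcome))
  if (anyNA(predicted) || any(predicted <= 0) || any(predicted >= 1))
    stop("predicted probabilities must lie strictly in (0, 1)")
  breaks <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(breaks) < 3) stop("predictions too heavily tied to form >= 2 groups")
  grp <- cut(predicted, breaks = breaks, include.lowest = TRUE)
  n_g <- as.numeric(table(grp))
  if (any(n_g == 0)) stop("empty group after tie merging")
  obs <- as.numeric(tapply(as.numeric(outcome), grp, sum))
  exp_ <- as.numeric(tapply(predicted, grp, sum))
  pbar <- exp_ / n_g
  chi2 <- sum((obs - exp_)^2 / (n_g * pbar * (1 - pbar)))
  g <- length(n_g)
  df <- as.integer(g - 2)
  structure(list(n_groups = g, observed = obs, expected = exp_, group_n = n_g,
                 chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f on %d df (g = %d), p = %.4g\n",
              x$chi2, x$df, x$n_groups, x$p))
  invisible(x)
}

#' Triage operating point at a target sensitivity
#'
#' For survival-oriented scores (lower score = sicker), a patient is triage
#' positive for death when `score < threshold`. Among all thresholds whose
#' sensitivity for the event reaches the target, returns the one with maximal
#' specificity — for a monotone score this is the smallest such threshold.
#' When even the all-positive rule cannot reach the target (impossible for a
#' finite threshold set; kept for contract completeness) the all-positive
#' point is returned with `attained = FALSE` and a warning.
#'
#' @param scores Numeric score vector, lower = higher event risk.
#' @param outcome Binary event (death) indicator.
#' @param target_sensitivity Required sensitivity, default 0.95.
#' @return An object of class `operating_point`: `threshold`, `sensitivity`,
#'   `specificity`, `target_sensitivity`, `attained`.
#' @export
operating_point <- function(scores, outcome, target_sensitivity = 0.95) {
  outcome <- .split_classes(outcome)
  if (length(scores) != length(outcome)) stop("length mismatch")
  thr <- c(sort(unique(scores)), Inf)
  ev <- scores[outcome]; nev <- scores[!outcome]
  sens <- vapply(thr, function(t) mean(ev < t), numeric(1))
  spec <- vapply(thr, function(t) mean(nev >= t), numeric(1))
  ok <- sens >= target_sensitivity
  if (!any(ok)) {
    warning("target sensitivity unattainable; returning all-positive point")
    i <- length(thr); attained <- FALSE
  } else {
    cand <- which(ok)
    i <- cand[which.max(spec[cand])]
    attained <- TRUE
  }
  structure(list(threshold = thr[i], sensitivity = sens[i],
                 specificity = spec[i],
                 target_sensitivity = target_sensitivity, attained = attained),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "Operating point: positive if score < %s; sensitivity %.3f, specificity %.3f (target %.2f%s)\n",
    format(x$threshold), x$sensitivity, x$specificity, x$target_sensitivity,
    if (x$attained) "" else ", NOT attained"))
  invisible(x)
}

#' Mortality by bins of a physiological variable
#'
#' Frequency-chart support: counts and death proportions in left-closed,
#' right-open bins of a variable (the display used to choose the NTS coding
#' intervals, e.g. revealing the bimodal SBP-mortality relationship).
#'
#' @param values Numeric vector.
#' @param outcome Binary death indicator.
#' @param bin_edges Strictly increasing numeric vector of bin edges; every
#'   value must fall in `[min(edges), max(edges))`.
#' @return A data frame with `bin_low`, `bin_high`, `count`, `deaths`,
#'   `mortality` (`NA` for empty bins).
#' @export
binned_mortality <- function(values, outcome, bin_edges) {
  stopifnot(length(values) == length(outcome))
  outcome <- as.logical(outcome)
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin_edges must be strictly increasing")
  if (any(values < bin_edges[1] | values >= bin_edges[length(bin_edges)]))
    stop("value outside all bins")
  idx <- findInterval(values, bin_edges)
  k <- length(bin_edges) - 1
  count <- tabulate(idx, nbins = k)
  deaths <- vapply(seq_len(k), function(i) sum(outcome[idx == i]), numeric(1))
  data.frame(bin_low = bin_edges[-length(bin_edges)], bin_high = bin_edges[-1],
             count = count, deaths = deaths,
             mortality = ifelse(count > 0, deaths / count, NA_real_))
}

#' Compare two cohorts variable by variable
#'
#' Descriptive comparison of two registries: continuous variables summarised
#' as median (IQR) and compared by the Mann-Whitney U test (normal
#' approximation with tie correction), categorical variables as n (%) with a
#' chi-squared test, all two-sided.
#'
#' @param a,b Trauma registry data frames.
#' @return A data frame of class `cohort_comparison` with columns `variable`,
#'   `summary_a`, `summary_b`, `test`, `p`.
#' @export
describe_cohort <- function(a, b) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  cont <- c("age", "sbp", "rr", "gcs", "spo2", "iss")
  rows <- list()
  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.4g (%.4g-%.4g)", q[2], q[1], q[3])
  }
  for (v in intersect(cont, intersect(names(a), names(b)))) {
    p <- stats::wilcox.test(a[[v]], b[[v]], exact = FALSE, correct = TRUE)$p.value
    rows[[v]] <- data.frame(variable = v, summary_a = med_iqr(a[[v]]),
                            summary_b = med_iqr(b[[v]]),
                            test = "mann_whitney", p = p)
  }
  cat_vars <- list(sex = "male", mechanism = "blunt", died = TRUE)
  n_pct <- function(x, lev) sprintf("%d (%.1f%%)", sum(x == lev, na.rm = TRUE),
                                    100 * mean(x == lev, na.rm = TRUE))
  for (v in intersect(names(cat_vars), intersect(names(a), names(b)))) {
    lev <- cat_vars[[v]]
    tab <- rbind(c(sum(a[[v]] == lev, na.rm = TRUE), sum(a[[v]] != lev, na.rm = TRUE)),
                 c(sum(b[[v]] == lev, na.rm = TRUE), sum(b[[v]] != lev, na.rm = TRUE)))
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    rows[[v]] <- data.frame(variable = v, summary_a = n_pct(a[[v]], lev),
                            summary_b = n_pct(b[[v]], lev),
                            test = "chi_squared", p = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_comparison", "data.frame")
  out
}
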