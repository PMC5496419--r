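#' Specification of a synthetic trauma cohort
#'
#' Parameters of the synthetic trauma-registry generator. The defaults
#' reproduce the derivation cohort's published marginals: n = 3263, median
#' age 60 (IQR 46-73), 66.0% male, 94.4% blunt mechanism, median SBP 130
#' (IQR 110-140), median RR 20 (IQR 18-20), median GCS 15, median SpO2 98
#' (IQR 96-99), in-hospital mortality 11.3%, and missingness rates of 8.9%
#' for ISS, 3.2% for SpO2 and 0.1% for SBP/RR/GCS. Survival is generated
#' from the published NTS logistic model, so the generator's outcome law is
#' exactly the model the derivation machinery is meant to recover.
#'
#' Covariates come from a two-component mixture: a "stable" component
#' concentrated at normal vitals (GCS 15, SpO2 around 98, RR around 20, SBP
#' around 130) and an "injured" component with depressed GCS and SpO2 and
#' dispersed SBP including a hypertensive tail above 150 mmHg, so that
#' abnormal vitals co-occur and mortality against SBP is bimodal. The mixing
#' weight (`severe_fraction = 0.305`) was calibrated once against the
#' marginal targets above and is frozen.
#'
#' @param n Cohort size.
#' @param seed Integer seed for [simulate_registry()].
#' @param male_fraction,blunt_fraction,severe_fraction Mixture and
#'   demographic fractions in `[0, 1]`.
#' @param outcome_coefficients A [score_coefficients()] object driving the
#'   Bernoulli survival draw via [ps()].
#' @param missingness Named per-variable missing-completely-at-random rates.
#' @param label Registry label.
#' @return An object of class `cohort_spec`.
#' @export
default_cohort_spec <- function(n = 3263, seed = 1, male_fraction = 0.66,
                                blunt_fraction = 0.944, severe_fraction = 0.305,
                                outcome_coefficients = score_coefficients(),
                                missingness = c(gcs = 0.001, sbp = 0.001,
                                                rr = 0.001, spo2 = 0.032,
                                                iss = 0.089),
                                label = "synthetic-derivation") {
  stopifnot(n >= 1, male_fraction >= 0, male_fraction <= 1,
            blunt_fraction >= 0, blunt_fraction <= 1,
            severe_fraction >= 0, severe_fraction <= 1,
            inherits(outcome_coefficients, "score_coefficients"),
            all(missingness >= 0), all(missingness < 1))
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    male_fraction = male_fraction, blunt_fraction = blunt_fraction,
    severe_fraction = severe_fraction,
    quantile_targets = list(age = c(q1 = 46, median = 60, q3 = 73),
                            sbp = c(q1 = 110, median = 130, q3 = 140),
                            rr = c(q1 = 18, median = 20, q3 = 20),
                            gcs = c(q1 = 15, median = 15, q3 = 15),
                            spo2 = c(q1 = 96, median = 98, q3 = 99)),
    outcome_coefficients = outcome_coefficients,
    missingness = missingness, label = label), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec '%s': n = %d, seed = %d\n", x$label, x$n, x$seed))
  cat(sprintf("  male %.1f%%, blunt %.1f%%, injured component %.1f%%\n",
              100 * x$male_fraction, 100 * x$blunt_fraction,
              100 * x$severe_fraction))
  cat("  missingness:", paste(sprintf("%s %.1f%%", names(x$missingness),
                                      100 * x$missingness), collapse = ", "), "\n")
  invisible(x)
}

.spo2_normal <- function(n)
  sample(94:100, n, replace = TRUE,
         prob = c(0.04, 0.06, 0.16, 0.12, 0.28, 0.19, 0.15))

.rr_stable <- function(n)
  sample(c(16, 18, 19, 20, 22, 24), n, replace = TRUE,
         prob = c(0.10, 0.25, 0.05, 0.40, 0.12, 0.08))

#' Simulate a synthetic trauma registry
#'
#' Draws a registry of `spec$n` patients from the mixture described in
#' [default_cohort_spec()], generates survival as
#' `Bernoulli(Ps(gcs, sbp_code, spo2_code))` under
#' `spec$outcome_coefficients`, and (optionally) injects
#' missing-completely-at-random cells at `spec$missingness` rates. Fully
#' reproducible from `spec$seed`. ISS is drawn as a severity-correlated
#' ordinal (log-normal around a T-NTS-dependent centre) and carries no
#' anatomical meaning; it exists as an imputation covariate.
#'
#' @param spec A [default_cohort_spec()] object.
#' @param missingness Inject MCAR missingness at the spec's rates (default
#'   `TRUE`).
#' @return A `trauma_registry` data frame with a `true_ps` attribute holding
#'   each patient's generating survival probability (before missingness).
#' @export
simulate_registry <- function(spec = default_cohort_spec(), missingness = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$severe_fraction == 0)
    warning("severe_fraction 0: cohort will be almost entirely low-risk")
  set.seed(spec$seed)
  n <- spec$n
  injured <- stats::runif(n) < spec$severe_fraction
  n_inj <- sum(injured); n_st <- n - n_inj
  gcs <- integer(n); sbp <- numeric(n); spo2 <- numeric(n); rr <- numeric(n)
  # stable component: normal physiology
  gcs[!injured] <- sample(c(15L, 14L), n_st, TRUE, prob = c(0.97, 0.03))
  spo2[!injured] <- .spo2_normal(n_st)
  sbp[!injured] <- round(pmax(70, stats::rnorm(n_st, 130, 18)))
  rr[!injured] <- .rr_stable(n_st)
  # injured component: depressed GCS/SpO2, dispersed SBP with hypertensive tail
  gcs[injured] <- sample(15:3, n_inj, TRUE,
    prob = c(0.20, 0.08, 0.06, 0.05, 0.05, 0.05, 0.06, 0.07, 0.07, 0.08,
             0.08, 0.07, 0.08))
  hypox <- stats::runif(n_inj) < 0.40
  s_inj <- numeric(n_inj)
  s_inj[!hypox] <- .spo2_normal(sum(!hypox))
  s_inj[hypox] <- round(pmin(100, pmax(20, stats::rnorm(sum(hypox), 82, 14))))
  spo2[injured] <- s_inj
  comp <- sample(1:3, n_inj, TRUE, prob = c(0.40, 0.35, 0.25))
  sbp[injured] <- round(pmax(0, stats::rnorm(n_inj, c(95, 130, 168)[comp],
                                             c(28, 15, 16)[comp])))
  abn <- stats::runif(n_inj) < 0.5
  r_inj <- numeric(n_inj)
  r_inj[!abn] <- .rr_stable(sum(!abn))
  r_inj[abn] <- sample(c(8, 10, 12, 24, 28, 32, 36), sum(abn), TRUE,
                       prob = c(0.15, 0.20, 0.15, 0.20, 0.14, 0.10, 0.06))
  rr[injured] <- r_inj
  age <- pmin(105, pmax(15, round(stats::rnorm(n, 60, 20))))
  sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  mechanism <- ifelse(stats::runif(n) < spec$blunt_fraction, "blunt", "penetrating")
  sbp_code <- code_sbp_nts(sbp); spo2_code <- code_spo2_nts(spo2)
  true_ps <- ps(gcs, sbp_code, spo2_code, spec$outcome_coefficients)
  died <- stats::runif(n) > true_ps
  tnts <- gcs + sbp_code + spo2_code
  iss <- pmin(75, pmax(1, round(exp(stats::rnorm(n, log(8) + 0.09 * (23 - tnts), 0.55)))))
  reg <- data.frame(age = age, sex = sex, mechanism = mechanism, gcs = gcs,
                    sbp = sbp, rr = rr, spo2 = spo2,
                    spo2_nm = FALSE, iss = iss, died = died)
  if (missingness && any(spec$missingness > 0))
    reg <- inject_missingness(reg, spec$missingness,
                              seed = spec$seed + 500009L)
  structure(reg, label = spec$label, true_ps = true_ps,
            class = c("trauma_registry", "data.frame"))
}

#' Inject missing-completely-at-random cells
#'
#' Masks each named variable independently at the given per-variable rate.
#' The input registry is untouched; masking is reproducible from `seed`.
#' Non-measurable SpO2 cells are never masked (they are already informative).
#'
#' @param registry A trauma registry data frame.
#' @param rates Named numeric vector of rates in `[0, 1)`, names matching
#'   registry columns.
#' @param seed Integer seed.
#' @return The registry with `NA`s injected.
#' @export
inject_missingness <- function(registry, rates, seed = 1) {
  stopifnot(is.data.frame(registry), all(rates >= 0), all(rates < 1),
            !is.null(names(rates)))
  set.seed(as.integer(seed))
  nm <- if ("spo2_nm" %in% names(registry)) registry$spo2_nm else
    rep(FALSE, nrow(registry))
  out <- registry
  for (v in names(rates)) {
    if (!v %in% names(out) || rates[[v]] == 0) next
    mask <- stats::runif(nrow(out)) < rates[[v]]
    if (v == "spo2") mask <- mask & !nm
    out[[v]][mask] <- NA
  }
  out
}
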