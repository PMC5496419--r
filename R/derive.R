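#' Run the full NTS derivation ladder on a complete registry
#'
#' Reproduces the derivation analysis on a registry with complete vitals
#' (run after imputation): univariate odds ratios for GCS, SBP, RR and SpO2
#' as continuous covariates and for the coded GCS value against the code-4
#' reference; the two multivariate contrasts (GCS + SBP + RR versus
#' GCS + SBP + SpO2, continuous) that motivated replacing RR with SpO2; the
#' final survival model on the actual GCS plus the NTS-coded SBP and SpO2;
#' the alternative model on the coded GCS; and discrimination (AUC for
#' death) and Hosmer-Lemeshow calibration of the final model. Survival is
#' the modelled outcome throughout, so higher vitals carry positive
#' coefficients and odds ratios above 1.
#'
#' @param registry A trauma registry data frame with complete `gcs`, `sbp`,
#'   `rr`, `spo2` and `died`.
#' @param n_groups Hosmer-Lemeshow group count.
#' @return An object of class `nts_derivation`: list with `univariate` (list
#'   of [univariate_or()] tables), `multivariate_rr` and `multivariate_spo2`
#'   (`logistic_fit`s), `final` and `final_coded_gcs` (`logistic_fit`s),
#'   `coefficients` (a [score_coefficients()] built from the final fit),
#'   `auc` (death discrimination of the final model) and `calibration`
#'   (a `calibration_result`), plus `n`.
#' @examples
#' reg <- simulate_registry(default_cohort_spec(n = 2000, seed = 42),
#'                          missingness = FALSE)
#' d <- derive_nts(reg)
#' d$final
#' @export
derive_nts <- function(registry, n_groups = 10) {
  stopifnot(is.data.frame(registry))
  need <- c("gcs", "sbp", "rr", "spo2", "died")
  nm <- if ("spo2_nm" %in% names(registry)) registry$spo2_nm else
    rep(FALSE, nrow(registry))
  spo2 <- registry$spo2
  spo2[nm] <- 0
  for (f in need) {
    vals <- if (f == "spo2") spo2 else registry[[f]]
    if (anyNA(vals))
      stop("derivation requires complete data; '", f, "' has missing values")
  }
  surv <- !registry$died
  codes <- code_record(registry)
  univariate <- list(
    gcs = univariate_or(registry$gcs, surv),
    sbp = univariate_or(registry$sbp, surv),
    rr = univariate_or(registry$rr, surv),
    spo2 = univariate_or(spo2, surv),
    gcs_code = univariate_or(factor(codes$gcs_code_rts, levels = 4:0), surv)
  )
  multivariate_rr <- fit_logistic(
    data.frame(gcs = registry$gcs, sbp = registry$sbp, rr = registry$rr), surv)
  multivariate_spo2 <- fit_logistic(
    data.frame(gcs = registry$gcs, sbp = registry$sbp, spo2 = spo2), surv)
  final <- fit_logistic(
    data.frame(gcs = registry$gcs, sbp_code_nts = codes$sbp_code_nts,
               spo2_code_nts = codes$spo2_code_nts), surv)
  final_coded_gcs <- fit_logistic(
    data.frame(gcs_code = codes$gcs_code_rts, sbp_code_nts = codes$sbp_code_nts,
               spo2_code_nts = codes$spo2_code_nts), surv)
  death_prob <- 1 - final$fitted
  structure(list(
    univariate = univariate,
    multivariate_rr = multivariate_rr,
    multivariate_spo2 = multivariate_spo2,
    final = final,
    final_coded_gcs = final_coded_gcs,
    coefficients = coefficients_from_fit(final),
    auc = auc(death_prob, registry$died),
    calibration = hosmer_lemeshow(death_prob, registry$died,
                                  n_groups = n_groups),
    n = nrow(registry)
  ), class = "nts_derivation")
}

#' @export
print.nts_derivation <- function(x, ...) {
  cat(sprintf("NTS derivation on n = %d patients (outcome: survival)\n", x$n))
  b <- x$final$coefficients
  cat(sprintf("  final model: b = %.4f + %.4f*GCS + %.4f*SBP_code + %.4f*SpO2_code\n",
              b["(Intercept)"], b["gcs"], b["sbp_code_nts"], b["spo2_code_nts"]))
  cat(sprintf("  discrimination: AUC %.3f; calibration: H-L chi2 %.3f (p %.3f)\n",
              x$auc, x$calibration$chi2, x$calibration$p))
  or_rr <- exp(x$multivariate_rr$coefficients["rr"])
  or_sp <- exp(x$multivariate_spo2$coefficients["spo2"])
  cat(sprintf("  adjusted OR per unit: RR %.3f vs SpO2 %.3f\n", or_rr, or_sp))
  invisible(x)
}

#' Table-style AUC comparison of a score panel
#'
#' Compares the death discrimination of the NTS against each comparator
#' (RTS, MGAP, GAP by default) on a scored registry with DeLong's test,
#' plus Hosmer-Lemeshow calibration of the Ps predictions when present and
#' the triage operating point of each score at a target sensitivity.
#' Survival-oriented scores are negated for the event-AUC convention.
#'
#' @param scored A registry scored by [score_panel()] (columns `nts`, `rts`,
#'   `mgap`, `gap`, `ps`, `died`).
#' @param comparators Character vector of comparator columns.
#' @param target_sensitivity Sensitivity target for [operating_point()].
#' @return An object of class `nts_validation`: list with `auc` (named AUCs),
#'   `comparisons` (list of `roc_comparison`), `operating_points` (list of
#'   `operating_point`), `calibration` (`calibration_result` or `NULL`).
#' @export
validate_scores <- function(scored, comparators = c("rts", "mgap", "gap"),
                            target_sensitivity = 0.95) {
  stopifnot(all(c("nts", "died") %in% names(scored)),
            all(comparators %in% names(scored)))
  died <- scored$died
  aucs <- c(nts = auc(-scored$nts, died))
  comparisons <- list(); ops <- list(nts = operating_point(scored$nts, died,
                                                           target_sensitivity))
  for (cmp in comparators) {
    aucs[[cmp]] <- auc(-scored[[cmp]], died)
    comparisons[[cmp]] <- delong_compare(-scored$nts, -scored[[cmp]], died)
    ops[[cmp]] <- operating_point(scored[[cmp]], died, target_sensitivity)
  }
  calibration <- if ("ps" %in% names(scored))
    hosmer_lemeshow(1 - scored$ps, died) else NULL
  structure(list(auc = aucs, comparisons = comparisons,
                 operating_points = ops, calibration = calibration),
            class = "nts_validation")
}

#' @export
print.nts_validation <- function(x, ...) {
  cat("Score validation (event: in-hospital death)\n")
  for (nm in names(x$auc)) {
    line <- sprintf("  %-5s AUC %.4f", nm, x$auc[[nm]])
    if (nm %in% names(x$comparisons)) {
      cc <- x$comparisons[[nm]]
      line <- paste0(line, sprintf("  vs NTS: diff %+.4f, p = %.4g",
                                   -cc$difference, cc$p))
    }
    op <- x$operating_points[[nm]]
    line <- paste0(line, sprintf("  [sens %.2f / spec %.2f at < %s]",
                                 op$sensitivity, op$specificity,
                                 format(op$threshold)))
    cat(line, "\n")
  }
  if (!is.null(x$calibration))
    cat(sprintf("  Ps calibration: H-L chi2 %.3f, p = %.3f\n",
                x$calibration$chi2, x$calibration$p))
  invisible(x)
}

#' Observed mortality by T-NTS risk stratum
#'
#' Tabulates patient counts, deaths and observed mortality in the four T-NTS
#' risk strata (low 18-23, intermediate 12-17, high 6-11, very high 3-5).
#'
#' @param scored A registry scored by [score_panel()] (columns `t_nts`,
#'   `died`).
#' @return A data frame with `stratum`, `count`, `deaths`, `mortality`.
#' @export
stratum_mortality <- function(scored) {
  stopifnot(all(c("t_nts", "died") %in% names(scored)))
  strata <- risk_stratum(scored$t_nts)
  count <- as.integer(table(strata))
  deaths <- as.integer(tapply(scored$died, strata, sum, default = 0))
  data.frame(stratum = levels(strata), count = count, deaths = deaths,
             mortality = ifelse(count > 0, deaths / count, NA_real_))
}
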