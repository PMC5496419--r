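#' Score coefficients for the RTS and NTS equations
#'
#' Container for the weights of the two weighted scores. Defaults are the
#' published values: RTS weights (0.9368, 0.7326, 0.2908) for the GCS, SBP
#' and RR codes, and the NTS logistic coefficients (intercept -6.5406, GCS
#' 0.4006, SBP code 0.2983, SpO2 code 0.8709) with survival as the modelled
#' outcome. The defaults can be overridden, e.g. with weights refitted by
#' [derive_nts()], which separates "the NTS as published" from "the NTS
#' derivation procedure".
#'
#' @param rts_weights Numeric length-3 vector of RTS weights in the order
#'   GCS code, SBP code, RR code.
#' @param nts_b0,nts_b_gcs,nts_b_sbp,nts_b_spo2 Intercept and coefficients of
#'   the survival logistic model behind the NTS (per GCS point, per SBP code
#'   point, per SpO2 code point).
#' @return An object of class `score_coefficients`.
#' @examples
#' score_coefficients()
#' @export
score_coefficients <- function(rts_weights = c(0.9368, 0.7326, 0.2908),
                               nts_b0 = -6.5406, nts_b_gcs = 0.4006,
                               nts_b_sbp = 0.2983, nts_b_spo2 = 0.8709) {
  stopifnot(length(rts_weights) == 3, is.numeric(rts_weights),
            is.numeric(nts_b0), is.numeric(nts_b_gcs),
            is.numeric(nts_b_sbp), is.numeric(nts_b_spo2))
  structure(list(rts_weights = unname(rts_weights), nts_b0 = nts_b0,
                 nts_b_gcs = nts_b_gcs, nts_b_sbp = nts_b_sbp,
                 nts_b_spo2 = nts_b_spo2),
            class = "score_coefficients")
}

#' @export
print.score_coefficients <- function(x, ...) {
  cat("Score coefficients\n")
  cat(sprintf("  RTS weights (GCS/SBP/RR codes): %.4f / %.4f / %.4f\n",
              x$rts_weights[1], x$rts_weights[2], x$rts_weights[3]))
  cat(sprintf("  NTS: b0 %.4f, GCS %.4f, SBP code %.4f, SpO2 code %.4f\n",
              x$nts_b0, x$nts_b_gcs, x$nts_b_sbp, x$nts_b_spo2))
  invisible(x)
}

#' Extract score coefficients from a fitted survival model
#'
#' Converts a [fit_logistic()] fit of survival on `gcs`, `sbp_code_nts` and
#' `spo2_code_nts` into a [score_coefficients()] object, so that refitted
#' weights can drive [nts()] and [ps()]. With such an override the NTS linear
#' predictor reproduces the model's linear predictor exactly.
#'
#' @param fit A `logistic_fit` whose coefficient names include `gcs`,
#'   `sbp_code_nts` and `spo2_code_nts`.
#' @param rts_weights Passed through unchanged.
#' @return A `score_coefficients` object.
#' @export
coefficients_from_fit <- function(fit, rts_weights = c(0.9368, 0.7326, 0.2908)) {
  stopifnot(inherits(fit, "logistic_fit"))
  b <- fit$coefficients
  need <- c("gcs", "sbp_code_nts", "spo2_code_nts")
  if (!all(need %in% names(b)))
    stop("fit must have coefficients named gcs, sbp_code_nts, spo2_code_nts")
  score_coefficients(rts_weights = rts_weights,
                     nts_b0 = unname(b["(Intercept)"]),
                     nts_b_gcs = unname(b["gcs"]),
                     nts_b_sbp = unname(b["sbp_code_nts"]),
                     nts_b_spo2 = unname(b["spo2_code_nts"]))
}

.check_code <- function(x, what) {
  bad <- !is.na(x) & !(x %in% 0:4)
  if (any(bad)) stop(sprintf("%s must be a code value in 0..4", what), call. = FALSE)
  x
}

#' Revised Trauma Score
#'
#' Weighted sum of the three RTS code values. The maximum, for normal vitals
#' (all codes 4), is 7.8408, conventionally reported as 7.84.
#'
#' @param gcs_code,sbp_code,rr_code Integer code values 0-4 from the RTS maps
#'   ([code_gcs_rts()], [code_sbp_rts()], [code_rr_rts()]).
#' @param coef A [score_coefficients()] object.
#' @return Numeric RTS at full precision; round to 2 decimals for reporting.
#' @examples
#' rts(4, 4, 4)  # 7.8408
#' @export
rts <- function(gcs_code, sbp_code, rr_code, coef = score_coefficients()) {
  .check_code(gcs_code, "gcs_code"); .check_code(sbp_code, "sbp_code")
  .check_code(rr_code, "rr_code")
  w <- coef$rts_weights
  w[1] * gcs_code + w[2] * sbp_code + w[3] * rr_code
}

#' New Trauma Score
#'
#' Weighted sum of the actual GCS score and the NTS code values for SBP and
#' SpO2: `b1*GCS + b2*SBP_code + b3*SpO2_code`. With the published
#' coefficients the attainable range is 1.2018 to 10.6858 (4-decimal
#' coefficient arithmetic).
#'
#' @param gcs Actual Glasgow Coma Scale score, integer 3-15.
#' @param sbp_code_nts,spo2_code_nts NTS code values 0-4 ([code_sbp_nts()],
#'   [code_spo2_nts()]).
#' @inheritParams rts
#' @return Numeric NTS at full precision.
#' @examples
#' nts(15, 4, 4)
#' @export
nts <- function(gcs, sbp_code_nts, spo2_code_nts, coef = score_coefficients()) {
  .check_domain(gcs, 3, 15, "gcs", integer = TRUE)
  .check_code(sbp_code_nts, "sbp_code_nts"); .check_code(spo2_code_nts, "spo2_code_nts")
  coef$nts_b_gcs * gcs + coef$nts_b_sbp * sbp_code_nts + coef$nts_b_spo2 * spo2_code_nts
}

#' Predicted survival probability
#'
#' The logistic transform of the NTS linear predictor,
#' `Ps = 1 / (1 + exp(-b))` with `b = b0 + b1*GCS + b2*SBP_code +
#' b3*SpO2_code`, interpreted as the probability of surviving to hospital
#' discharge.
#'
#' @inheritParams nts
#' @return Probability strictly between 0 and 1.
#' @examples
#' ps(15, 4, 4)
#' @export
ps <- function(gcs, sbp_code_nts, spo2_code_nts, coef = score_coefficients()) {
  stats::plogis(coef$nts_b0 + nts(gcs, sbp_code_nts, spo2_code_nts, coef))
}

#' T-NTS: the unweighted triage sum
#'
#' Dropping the regression coefficients from the NTS gives an integer triage
#' score, `T-NTS = GCS + SBP_code + SpO2_code`, ranging from 3 to 23.
#'
#' @inheritParams nts
#' @return Integer in 3-23.
#' @examples
#' t_nts(15, 4, 4)  # 23
#' @export
t_nts <- function(gcs, sbp_code_nts, spo2_code_nts) {
  .check_domain(gcs, 3, 15, "gcs", integer = TRUE)
  .check_code(sbp_code_nts, "sbp_code_nts"); .check_code(spo2_code_nts, "spo2_code_nts")
  as.integer(gcs + sbp_code_nts + spo2_code_nts)
}

#' Risk strata and the triage-transfer rule for the T-NTS
#'
#' Partitions the T-NTS range into four mortality-risk strata: low (18-23),
#' intermediate (12-17), high (6-11) and very high (3-5). `triage_transfer()`
#' flags patients below the transfer cutoff (default 18, the operating point
#' at which the derivation-cohort sensitivity for death reached 95%) for
#' transfer to a trauma centre.
#'
#' @param t_nts Integer T-NTS values in 3-23.
#' @param cutoff Transfer cutoff; scores strictly below it are flagged.
#' @return `risk_stratum()`: a factor with levels `low`, `intermediate`,
#'   `high`, `very_high`. `triage_transfer()`: a logical vector.
#' @examples
#' risk_stratum(c(18, 17, 5))
#' triage_transfer(c(18, 17))
#' @export
risk_stratum <- function(t_nts) {
  .check_domain(t_nts, 3, 23, "t_nts", integer = TRUE)
  cut(t_nts, breaks = c(2, 5, 11, 17, 23),
      labels = c("very_high", "high", "intermediate", "low")) |>
    factor(levels = c("low", "intermediate", "high", "very_high"))
}

#' @rdname risk_stratum
#' @export
triage_transfer <- function(t_nts, cutoff = 18) {
  .check_domain(t_nts, 3, 23, "t_nts", integer = TRUE)
  t_nts < cutoff
}

#' MGAP and GAP comparator scores
#'
#' Point-additive physiological scores combining the actual GCS with age and
#' SBP bands (MGAP also scores a blunt mechanism). The point assignments are
#' not restated in the NTS source and are frozen here from the scores'
#' original publications: MGAP = GCS + 5 (age < 60) + 4 (blunt) +
#' \{5 if SBP >= 120; 3 if 60 <= SBP < 120; 0 if SBP < 60\}, range 3-29;
#' GAP = GCS + 3 (age < 60) + \{6 if SBP > 120; 4 if 60 <= SBP <= 120;
#' 0 if SBP < 60\}, range 3-24. GAP's SBP band boundary is taken so that
#' exactly 120 mmHg falls in the middle band; [coding_reference()] users
#' should note secondary sources differ on this point.
#'
#' @param gcs Actual GCS, integer 3-15.
#' @param age Age in years.
#' @param mechanism Character, `"blunt"` or `"penetrating"`.
#' @param sbp Systolic blood pressure, mmHg.
#' @return Integer score.
#' @examples
#' mgap(15, 40, "blunt", 130)  # 29
#' gap(15, 40, 130)            # 24
#' @export
mgap <- function(gcs, age, mechanism, sbp) {
  .check_domain(gcs, 3, 15, "gcs", integer = TRUE)
  .check_domain(age, 0, Inf, "age"); .check_domain(sbp, 0, Inf, "sbp")
  if (!all(is.na(mechanism) | mechanism %in% c("blunt", "penetrating")))
    stop("mechanism must be 'blunt' or 'penetrating'")
  as.integer(gcs + 5L * (age < 60) + 4L * (mechanism == "blunt") +
               ifelse(sbp >= 120, 5L, ifelse(sbp >= 60, 3L, 0L)))
}

#' @rdname mgap
#' @export
gap <- function(gcs, age, sbp) {
  .check_domain(gcs, 3, 15, "gcs", integer = TRUE)
  .check_domain(age, 0, Inf, "age"); .check_domain(sbp, 0, Inf, "sbp")
  as.integer(gcs + 3L * (age < 60) +
               ifelse(sbp > 120, 6L, ifelse(sbp >= 60, 4L, 0L)))
}

#' Score a registry: the full score panel
#'
#' Codes every record and computes all scores: RTS, NTS, predicted survival
#' (Ps), T-NTS, MGAP, GAP and the T-NTS risk stratum. Requires complete
#' vitals (run after imputation); by default a missing required field is an
#' error naming the field.
#'
#' @param registry A trauma registry data frame with columns `age`, `sex`,
#'   `mechanism`, `gcs`, `sbp`, `rr`, `spo2` (and optionally `spo2_nm`).
#' @param coef A [score_coefficients()] object.
#' @param on_missing `"error"` (default) stops naming the first field with
#'   missing values; `"na"` propagates `NA` scores instead.
#' @return The registry with columns `rts`, `nts`, `t_nts`, `ps`, `mgap`,
#'   `gap`, `stratum` appended.
#' @export
score_panel <- function(registry, coef = score_coefficients(),
                        on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  need <- c("age", "mechanism", "gcs", "sbp", "rr", "spo2")
  missing_cols <- setdiff(need, names(registry))
  if (length(missing_cols))
    stop("registry lacks required columns: ", paste(missing_cols, collapse = ", "))
  nm <- if ("spo2_nm" %in% names(registry)) registry$spo2_nm else
    rep(FALSE, nrow(registry))
  if (on_missing == "error") {
    for (f in need) {
      vals <- registry[[f]]
      if (f == "spo2") vals[nm] <- 0  # non-measurable is informative, not missing
      if (anyNA(vals))
        stop(sprintf("missing values in required field '%s' (%d rows); impute first",
                     f, sum(is.na(vals))), call. = FALSE)
    }
  }
  codes <- code_record(registry)
  out <- registry
  out$rts <- rts(codes$gcs_code_rts, codes$sbp_code_rts, codes$rr_code_rts, coef)
  out$nts <- nts(registry$gcs, codes$sbp_code_nts, codes$spo2_code_nts, coef)
  out$t_nts <- t_nts(registry$gcs, codes$sbp_code_nts, codes$spo2_code_nts)
  out$ps <- ps(registry$gcs, codes$sbp_code_nts, codes$spo2_code_nts, coef)
  out$mgap <- mgap(registry$gcs, registry$age, registry$mechanism, registry$sbp)
  out$gap <- gap(registry$gcs, registry$age, registry$sbp)
  out$stratum <- risk_stratum(out$t_nts)
  out
}
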