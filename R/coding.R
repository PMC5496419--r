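#' Code-value maps for the RTS and the NTS
#'
#' The Revised Trauma Score (RTS) converts Glasgow Coma Scale (GCS), systolic
#' blood pressure (SBP) and respiratory rate (RR) to integer code values 0-4.
#' The New Trauma Score (NTS) keeps the actual GCS but recodes SBP on revised
#' intervals (with a hypertension band scoring 3) and replaces RR with
#' peripheral oxygen saturation (SpO2). These functions implement the five
#' maps; all are vectorised and propagate `NA`.
#'
#' The published tables print integer interval endpoints. For real-valued
#' inputs each code interval is taken as closed at its printed lower endpoint
#' and open at the next interval's lower endpoint, so e.g. an SBP of 89.5
#' codes as 3 under the RTS (">89" realised as `[90, Inf)` for reals) and
#' 149.5 codes as 4 under the NTS (`[110, 150)`). This closes the real-number
#' gaps the integer tables leave open while agreeing with the tables on every
#' integer input.
#'
#' @param gcs Glasgow Coma Scale score, integer in 3-15.
#' @param sbp Systolic blood pressure in mmHg, non-negative.
#' @param rr Respiratory rate in breaths per minute, non-negative.
#' @param spo2 Peripheral oxygen saturation in percent, in \[0, 100\].
#' @param non_measurable Logical, recycled along `spo2`: `TRUE` marks an SpO2
#'   that could not be measured (profound shock, arrest). Non-measurable SpO2
#'   codes as 0, the floor of the map, regardless of the numeric value.
#' @return Integer vector of code values in 0-4 (`NA` where the input is
#'   missing).
#' @examples
#' code_gcs_rts(3:15)
#' code_sbp_nts(c(130, 150, 90, 69.9))
#' code_spo2_nts(c(98, 85, NA), non_measurable = c(FALSE, FALSE, TRUE))
#' @name coding
NULL

.check_domain <- function(x, lo, hi, what, integer = FALSE) {
  bad <- !is.na(x) & (x < lo | x > hi | (integer & x != round(x)))
  if (any(bad))
    stop(sprintf("%s out of domain [%s, %s]%s: %s", what, lo, hi,
                 if (integer) " (integer)" else "",
                 paste(utils::head(x[bad], 5), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

#' @rdname coding
#' @export
code_gcs_rts <- function(gcs) {
  .check_domain(gcs, 3, 15, "gcs", integer = TRUE)
  ifelse(gcs >= 13, 4L, ifelse(gcs >= 9, 3L, ifelse(gcs >= 6, 2L,
    ifelse(gcs >= 4, 1L, 0L))))
}

#' @rdname coding
#' @export
code_sbp_rts <- function(sbp) {
  .check_domain(sbp, 0, Inf, "sbp")
  ifelse(sbp >= 90, 4L, ifelse(sbp >= 76, 3L, ifelse(sbp >= 50, 2L,
    ifelse(sbp > 0, 1L, 0L))))
}

#' @rdname coding
#' @export
code_rr_rts <- function(rr) {
  .check_domain(rr, 0, Inf, "rr")
  ifelse(rr >= 30, 3L, ifelse(rr >= 10, 4L, ifelse(rr >= 6, 2L,
    ifelse(rr > 0, 1L, 0L))))
}

#' @rdname coding
#' @export
code_sbp_nts <- function(sbp) {
  .check_domain(sbp, 0, Inf, "sbp")
  ifelse(sbp >= 150, 3L, ifelse(sbp >= 110, 4L, ifelse(sbp >= 90, 2L,
    ifelse(sbp >= 70, 1L, 0L))))
}

#' @rdname coding
#' @export
code_spo2_nts <- function(spo2, non_measurable = FALSE) {
  non_measurable <- rep_len(non_measurable, length(spo2))
  non_measurable[is.na(non_measurable)] <- FALSE
  .check_domain(spo2[!non_measurable], 0, 100, "spo2")
  out <- ifelse(spo2 >= 94, 4L, ifelse(spo2 >= 80, 3L, ifelse(spo2 >= 60, 2L,
    ifelse(spo2 >= 40, 1L, 0L))))
  out[non_measurable] <- 0L
  out
}

#' Apply all five code maps to a registry
#'
#' Derives the RTS codes (GCS, SBP, RR) and NTS codes (SBP, SpO2) for every
#' record. The NTS uses the actual GCS score, so no NTS GCS code exists.
#' Missingness propagates field-wise: a code is `NA` exactly when its
#' underlying vital is missing (a non-measurable SpO2 is not missing — it
#' codes as 0).
#'
#' @param registry A trauma registry data frame (see [read_registry()]) with
#'   columns `gcs`, `sbp`, `rr`, `spo2` and optionally the logical `spo2_nm`.
#' @return A data frame with columns `gcs_code_rts`, `sbp_code_rts`,
#'   `rr_code_rts`, `sbp_code_nts`, `spo2_code_nts`, one row per record.
#' @export
code_record <- function(registry) {
  stopifnot(is.data.frame(registry))
  nm <- if ("spo2_nm" %in% names(registry)) registry$spo2_nm else FALSE
  data.frame(
    gcs_code_rts  = code_gcs_rts(registry$gcs),
    sbp_code_rts  = code_sbp_rts(registry$sbp),
    rr_code_rts   = code_rr_rts(registry$rr),
    sbp_code_nts  = code_sbp_nts(registry$sbp),
    spo2_code_nts = code_spo2_nts(registry$spo2, non_measurable = nm)
  )
}

#' Machine-readable coding tables
#'
#' Returns the five code-value maps as a nested list (suitable for
#' `jsonlite::toJSON`) for documentation and cross-language checks. Bounds are
#' the real-valued convention described in [coding]: each interval is
#' `[lower, upper)`.
#'
#' @param path Optional file path; when given, the reference is written as
#'   JSON and the path returned invisibly.
#' @return A nested list of maps, each a list of `list(code, lower, upper)`.
#' @export
coding_reference <- function(path = NULL) {
  iv <- function(code, lower, upper) list(code = code, lower = lower, upper = upper)
  ref <- list(
    gcs_rts  = list(iv(4L, 13, 16), iv(3L, 9, 13), iv(2L, 6, 9), iv(1L, 4, 6), iv(0L, 3, 4)),
    sbp_rts  = list(iv(4L, 90, Inf), iv(3L, 76, 90), iv(2L, 50, 76), iv(1L, 1e-12, 50), iv(0L, 0, 1e-12)),
    rr_rts   = list(iv(3L, 30, Inf), iv(4L, 10, 30), iv(2L, 6, 10), iv(1L, 1e-12, 6), iv(0L, 0, 1e-12)),
    sbp_nts  = list(iv(3L, 150, Inf), iv(4L, 110, 150), iv(2L, 90, 110), iv(1L, 70, 90), iv(0L, 0, 70)),
    spo2_nts = list(iv(4L, 94, 101), iv(3L, 80, 94), iv(2L, 60, 80), iv(1L, 40, 60), iv(0L, 0, 40))
  )
  if (!is.null(path)) {
    jsonlite::write_json(ref, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  ref
}
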