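#' Trauma registry tables
#'
#' A trauma registry is a data frame with one row per patient and the
#' canonical columns `age` (years, integer), `sex` (`"male"`/`"female"`),
#' `mechanism` (injury mechanism; analyses use `"blunt"`/`"penetrating"`),
#' `gcs` (integer 3-15), `sbp` (mmHg), `rr` (breaths/min), `spo2` (percent),
#' `iss` (Injury Severity Score, integer 1-75) and `died` (logical,
#' in-hospital death). A logical companion column `spo2_nm` marks
#' non-measurable SpO2, which is clinically informative (profound shock) and
#' kept distinct from missing-at-random SpO2. Optional logical columns
#' `dead_on_arrival` and `ed_discharge` support the exclusion flow of
#' [apply_cohort_filter()]. Any field other than `age`, `sex`, `mechanism`
#' and `died` may be missing (`NA`).
#'
#' @name trauma_registry
NULL

.canonical_cols <- c("age", "sex", "mechanism", "gcs", "sbp", "rr", "spo2",
                     "iss", "died")

.parse_died <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "t")] <- TRUE
  out[x %in% c("0", "false", "no", "f")] <- FALSE
  out
}

#' Validate registry rows
#'
#' Checks the hard per-field invariants (GCS an integer in 3-15, SpO2 in
#' 0-100, SBP and RR non-negative, ISS an integer in 1-75, age a non-negative
#' integer, sex one of male/female, died interpretable as a boolean). Missing
#' values are allowed everywhere the data model allows them; violations are
#' enumerated row by row, never silently coerced.
#'
#' @param df A data frame with (at least) the canonical columns.
#' @return A list with `valid`, a logical vector over rows, and
#'   `diagnostics`, a data frame with columns `row`, `field`, `problem`.
#' @export
validate_registry <- function(df) {
  n <- nrow(df)
  diags <- list()
  flag <- function(rows, field, problem) {
    if (any(rows)) diags[[length(diags) + 1]] <<-
        data.frame(row = which(rows), field = field, problem = problem)
  }
  flag(!is.na(df$gcs) & (df$gcs < 3 | df$gcs > 15 | df$gcs != round(df$gcs)),
       "gcs", "must be an integer in [3, 15]")
  flag(!is.na(df$spo2) & (df$spo2 < 0 | df$spo2 > 100),
       "spo2", "must lie in [0, 100]")
  flag(!is.na(df$sbp) & df$sbp < 0, "sbp", "must be non-negative")
  flag(!is.na(df$rr) & df$rr < 0, "rr", "must be non-negative")
  flag(!is.na(df$iss) & (df$iss < 1 | df$iss > 75 | df$iss != round(df$iss)),
       "iss", "must be an integer in [1, 75]")
  flag(is.na(df$age) | df$age < 0 | df$age != round(df$age),
       "age", "must be a non-negative integer")
  flag(is.na(df$sex) | !df$sex %in% c("male", "female"),
       "sex", "must be 'male' or 'female'")
  flag(is.na(df$mechanism) | !nzchar(df$mechanism),
       "mechanism", "must be non-missing")
  flag(is.na(df$died), "died", "must be TRUE/FALSE (1/0)")
  diagnostics <- if (length(diags)) do.call(rbind, diags) else
    data.frame(row = integer(), field = character(), problem = character())
  valid <- rep(TRUE, n)
  valid[diagnostics$row] <- FALSE
  list(valid = valid, diagnostics = diagnostics[order(diagnostics$row), ])
}

#' Read a trauma registry from delimited text
#'
#' Reads a delimited text file with a header row into a validated trauma
#' registry. Empty cells and `"NA"` read as missing; the sentinel token
#' `"NM"` in the `spo2` column reads as non-measurable SpO2 (`spo2 = NA`,
#' `spo2_nm = TRUE`). Column names can be mapped from local registry
#' conventions via `aliases`. Rows violating hard invariants (e.g. a GCS of
#' 2) are rejected with row-indexed diagnostics, available through
#' `attr(reg, "rejected")` and reported in a warning.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, default `","`.
#' @param aliases Named character vector mapping file column names to
#'   canonical names, e.g. `c(systolic_bp = "sbp")`.
#' @param label Free-text label for the registry (e.g. "derivation").
#' @return A `trauma_registry` data frame; attributes `label` and `rejected`.
#' @export
read_registry <- function(path, delim = ",", aliases = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), encoding = "UTF-8")
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- unname(aliases[names(raw)[hit]])
  }
  missing_cols <- setdiff(.canonical_cols, names(raw))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  blank <- function(x) !nzchar(trimws(x)) | trimws(x) == "NA"
  num <- function(x) suppressWarnings(as.numeric(ifelse(blank(x), NA, trimws(x))))
  spo2_raw <- trimws(raw$spo2)
  spo2_nm <- toupper(spo2_raw) == "NM"
  df <- data.frame(
    age = num(raw$age),
    sex = tolower(ifelse(blank(raw$sex), NA, trimws(raw$sex))),
    mechanism = tolower(ifelse(blank(raw$mechanism), NA, trimws(raw$mechanism))),
    gcs = num(raw$gcs), sbp = num(raw$sbp), rr = num(raw$rr),
    spo2 = num(ifelse(spo2_nm, "", spo2_raw)),
    spo2_nm = spo2_nm,
    iss = num(raw$iss),
    died = .parse_died(raw$died)
  )
  for (opt in c("dead_on_arrival", "ed_discharge"))
    if (opt %in% names(raw)) df[[opt]] <- .parse_died(raw[[opt]])
  v <- validate_registry(df)
  if (!any(v$valid)) stop("no valid rows in ", path)
  if (any(!v$valid)) {
    d <- v$diagnostics
    warning(sprintf("rejected %d row(s): %s", sum(!v$valid),
                    paste(sprintf("row %d [%s] %s", d$row, d$field, d$problem),
                          collapse = "; ")), call. = FALSE)
  }
  out <- df[v$valid, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = label, rejected = v$diagnostics,
            class = c("trauma_registry", "data.frame"))
}

#' Write a trauma registry to delimited text
#'
#' Inverse of [read_registry()]: canonical header, missing values written as
#' empty fields, non-measurable SpO2 written as the sentinel token `"NM"`.
#' Reading the file back reproduces the registry cell for cell.
#'
#' @param registry A trauma registry data frame (non-empty).
#' @param path Output file path.
#' @param delim Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, delim = ",") {
  stopifnot(is.data.frame(registry), nrow(registry) > 0)
  cols <- intersect(c(.canonical_cols, "dead_on_arrival", "ed_discharge"),
                    names(registry))
  out <- registry[, cols, drop = FALSE]
  for (lg in intersect(c("died", "dead_on_arrival", "ed_discharge"), cols))
    out[[lg]] <- as.integer(out[[lg]])
  out$spo2 <- as.character(out$spo2)
  if ("spo2_nm" %in% names(registry)) out$spo2[registry$spo2_nm] <- "NM"
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.table(out, path, sep = delim, quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the cohort inclusion and exclusion criteria
#'
#' Retains patients with a blunt or penetrating injury mechanism and age >=
#' 15 years. When the optional logical columns `dead_on_arrival` or
#' `ed_discharge` are present, patients flagged `TRUE` are also excluded
#' (dead on ED arrival; discharged or transferred from the ED). The returned
#' tally counts rows removed per criterion, applied in the order mechanism,
#' age, dead-on-arrival, ED discharge (each row counted once, at the first
#' criterion it fails). The filter is idempotent.
#'
#' @param registry A trauma registry data frame.
#' @return A list with `registry` (the filtered registry) and `exclusions`
#'   (named integer tally).
#' @export
apply_cohort_filter <- function(registry) {
  stopifnot(is.data.frame(registry))
  excl_mech <- is.na(registry$mechanism) |
    !registry$mechanism %in% c("blunt", "penetrating")
  excl_age <- !excl_mech & (is.na(registry$age) | registry$age < 15)
  taken <- excl_mech | excl_age
  excl_doa <- rep(FALSE, nrow(registry))
  if ("dead_on_arrival" %in% names(registry))
    excl_doa <- !taken & !is.na(registry$dead_on_arrival) & registry$dead_on_arrival
  taken <- taken | excl_doa
  excl_ed <- rep(FALSE, nrow(registry))
  if ("ed_discharge" %in% names(registry))
    excl_ed <- !taken & !is.na(registry$ed_discharge) & registry$ed_discharge
  keep <- !(taken | excl_ed)
  out <- registry[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(registry, "label")
  list(registry = out,
       exclusions = c(mechanism = sum(excl_mech), age_under_15 = sum(excl_age),
                      dead_on_arrival = sum(excl_doa), ed_discharge = sum(excl_ed)))
}
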