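test_that("read_registry parses a small CSV preserving per-field missingness", {
  path <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "age,sex,mechanism,gcs,sbp,rr,spo2,iss,died",
    "40,male,blunt,15,130,20,98,4,0",
    "72,female,blunt,9,85,8,,25,1",
    "25,male,penetrating,15,160,22,97,9,0"))
  reg <- read_registry(path)
  expect_s3_class(reg, "trauma_registry")
  expect_identical(nrow(reg), 3L)
  expect_identical(is.na(reg$spo2), c(FALSE, TRUE, FALSE))
  expect_identical(reg$died, c(FALSE, TRUE, FALSE))
  expect_identical(nrow(attr(reg, "rejected")), 0L)
})

test_that("rows violating hard invariants are rejected with row-indexed diagnostics", {
  path <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "age,sex,mechanism,gcs,sbp,rr,spo2,iss,died",
    "40,male,blunt,15,130,20,98,4,0",
    "33,male,blunt,2,130,20,98,4,0",
    "51,female,blunt,15,120,18,97,5,1"))
  expect_warning(reg <- read_registry(path), "row 2 \\[gcs\\]")
  expect_identical(nrow(reg), 2L)
  rej <- attr(reg, "rejected")
  expect_identical(rej$row, 2L)
  expect_identical(rej$field, "gcs")
})

test_that("missing-value tokens: empty and NA read as missing, NM as non-measurable", {
  path <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "age,sex,mechanism,gcs,sbp,rr,spo2,iss,died",
    "40,male,blunt,15,130,20,NM,4,0",
    "41,male,blunt,15,130,20,NA,4,0",
    "42,male,blunt,15,130,20,,4,0"))
  reg <- read_registry(path)
  expect_identical(reg$spo2_nm, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(reg$spo2)))
  # non-measurable codes 0; missing-at-random stays missing
  codes <- code_record(reg)
  expect_identical(codes$spo2_code_nts, c(0L, NA, NA))
})

test_that("column aliases map local header names onto the canonical schema", {
  path <- write_toy_csv(tempfile(fileext = ".csv"), c(
    "age,sex,mechanism,gcs,systolic_bp,resp_rate,spo2,iss,died",
    "40,male,blunt,15,130,20,98,4,0"))
  reg <- read_registry(path, aliases = c(systolic_bp = "sbp", resp_rate = "rr"))
  expect_identical(reg$sbp, 130)
  expect_error(read_registry(path), "missing mandatory columns: sbp, rr")
})

test_that("write then read is the identity on a synthetic registry", {
  reg <- simulate_registry(default_cohort_spec(n = 100, seed = 11))
  reg$spo2_nm[5] <- TRUE; reg$spo2[5] <- NA  # exercise the NM sentinel
  path <- tempfile(fileext = ".csv")
  write_registry(reg, path)
  expect_match(strsplit(readLines(path, n = 6)[6], ",")[[1]][7], "^(NM|[0-9.]*)$")
  back <- read_registry(path)
  for (col in c("age", "sex", "mechanism", "gcs", "sbp", "rr", "spo2",
                "spo2_nm", "iss", "died"))
    expect_equal(back[[col]], reg[[col]], ignore_attr = TRUE, label = col)
})

test_that("write_registry emits the NM sentinel and empty fields for missing", {
  reg <- toy_registry()
  reg$spo2_nm[3] <- TRUE
  path <- tempfile(fileext = ".csv")
  write_registry(reg, path)
  lines <- readLines(path)
  expect_identical(lines[1], "age,sex,mechanism,gcs,sbp,rr,spo2,iss,died")
  expect_identical(length(lines), 4L)
  expect_match(lines[4], ",NM,")
  expect_error(write_registry(reg[0, ], tempfile()), "nrow")
})

test_that("cohort filter applies both inclusion criteria with a per-criterion tally", {
  reg <- data.frame(age = c(14L, 40L, 40L), sex = rep("male", 3),
                    mechanism = c("blunt", "blunt", "burn"),
                    gcs = 15L, sbp = 120, rr = 18, spo2 = 98,
                    iss = 5L, died = FALSE)
  out <- apply_cohort_filter(reg)
  expect_identical(nrow(out$registry), 1L)
  expect_identical(out$exclusions[["age_under_15"]], 1L)
  expect_identical(out$exclusions[["mechanism"]], 1L)
  # all-eligible registry: identity with zero tally
  ok <- reg[2, , drop = FALSE]
  out2 <- apply_cohort_filter(ok)
  expect_equal(out2$registry, ok, ignore_attr = TRUE)
  expect_true(all(out2$exclusions == 0L))
})

test_that("cohort filter honours optional exclusion flags and is idempotent", {
  reg <- simulate_registry(default_cohort_spec(n = 400, seed = 21))
  reg$age[1:40] <- sample(5:14, 40, replace = TRUE)  # inject 10% under-age
  reg$dead_on_arrival <- FALSE; reg$dead_on_arrival[41:45] <- TRUE
  reg$ed_discharge <- FALSE; reg$ed_discharge[46:50] <- TRUE
  out <- apply_cohort_filter(reg)
  expect_identical(out$exclusions[["age_under_15"]], 40L)
  expect_identical(out$exclusions[["dead_on_arrival"]], 5L)
  expect_identical(out$exclusions[["ed_discharge"]], 5L)
  expect_identical(nrow(out$registry), 350L)
  again <- apply_cohort_filter(out$registry)
  expect_true(all(again$exclusions == 0L))
  expect_equal(again$registry, out$registry, ignore_attr = TRUE)
})
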