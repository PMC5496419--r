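# small fixtures built in code

toy_registry <- function() {
  data.frame(
    age = c(40L, 72L, 25L),
    sex = c("male", "female", "male"),
    mechanism = c("blunt", "blunt", "penetrating"),
    gcs = c(15L, 9L, 15L),
    sbp = c(130, 85, 160),
    rr = c(20, 8, 22),
    spo2 = c(98, 75, NA),
    spo2_nm = c(FALSE, FALSE, FALSE),
    iss = c(4L, 25L, 9L),
    died = c(FALSE, TRUE, FALSE)
  )
}

write_toy_csv <- function(path, lines) {
  writeLines(lines, path)
  path
}

# O(n^2) pair-counting AUC oracle (midrank tie convention)
auc_pair_oracle <- function(scores, outcome) {
  ev <- scores[as.logical(outcome)]
  nev <- scores[!as.logical(outcome)]
  tot <- 0
  for (e in ev) tot <- tot + sum(e > nev) + 0.5 * sum(e == nev)
  tot / (length(ev) * length(nev))
}
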