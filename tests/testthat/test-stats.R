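test_that("fit_logistic recovers the closed-form intercept and flags pathologies", {
  y <- rep(c(1L, 0L), c(30, 70))
  fit <- fit_logistic(NULL, y)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(0.3 / 0.7),
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(unname(fit$se), sqrt(1 / 30 + 1 / 70), tolerance = 1e-6)
  # perfectly separated toy
  x <- c(-(5:1), 1:5); y2 <- as.integer(x > 0)
  expect_error(fit_logistic(data.frame(x = x), y2), "separation")
  expect_error(fit_logistic(data.frame(x = rep(1, 10)), rep(0:1, 5)), "constant")
  expect_error(fit_logistic(data.frame(x = rnorm(10)), rep(1L, 10)), "single class")
})

test_that("fit_logistic standard errors come from the information-matrix diagonal", {
  set.seed(71)
  x <- rnorm(500); y <- rbinom(500, 1, plogis(-1 + x))
  fit <- fit_logistic(data.frame(x = x), y)
  expect_equal(unname(fit$se), unname(sqrt(diag(fit$vcov))))
  expect_true(isSymmetric(fit$vcov, tol = 1e-12))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
})

test_that("univariate_or matches 2x2 cross-product arithmetic and reparameterization", {
  x <- rep(c("exposed", "unexposed"), c(100, 100))
  y <- c(rep(1:0, c(10, 90)), rep(1:0, c(50, 50)))
  res <- univariate_or(x, y, reference = "unexposed")
  expect_equal(res$or, (10 / 90) / (50 / 50), tolerance = 1e-6)
  expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
  # affine reparameterization: doubling x halves the log-OR
  set.seed(72)
  xc <- rnorm(400); yc <- rbinom(400, 1, plogis(0.8 * xc))
  or1 <- univariate_or(xc, yc)$or
  or2 <- univariate_or(2 * xc, yc)$or
  expect_equal(or2, or1^(1 / 2), tolerance = 1e-6)
})

test_that("categorical odds ratios match a direct contingency cross-product oracle", {
  set.seed(73)
  reg <- simulate_registry(default_cohort_spec(n = 6000, seed = 73),
                           missingness = FALSE)
  gcs_code <- factor(code_gcs_rts(reg$gcs), levels = 4:0)
  keep <- gcs_code %in% c(4, 3, 2)  # avoid near-empty extreme cells
  surv <- !reg$died[keep]
  x <- droplevels(gcs_code[keep])
  res <- univariate_or(x, surv)
  for (lev in c("3", "2")) {
    a <- sum(x == lev & surv);  b <- sum(x == lev & !surv)
    c_ <- sum(x == "4" & surv); d <- sum(x == "4" & !surv)
    expect_equal(res$or[res$term == lev], (a / b) / (c_ / d), tolerance = 1e-6)
  }
})

test_that("auc equals the exhaustive pair-counting statistic and handles edge cases", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(rep(1, 10), rep(0:1, 5)), 0.5)
  set.seed(74)
  for (i in 1:5) {
    s <- sample(1:40, 120, replace = TRUE)  # plenty of ties
    y <- rbinom(120, 1, plogis((s - 20) / 8))
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), auc_pair_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("auc is invariant under strictly increasing transforms and flips under negation", {
  set.seed(75)
  s <- rnorm(300); y <- rbinom(300, 1, plogis(s))
  a <- auc(s, y)
  expect_equal(auc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(auc(3 * s + 7, y), a, tolerance = 1e-12)
  expect_equal(auc(-s, y), 1 - a, tolerance = 1e-12)  # no ties in rnorm draws
})

test_that("delong_compare is degenerate-safe and antisymmetric", {
  set.seed(76)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(2 * s))
  same <- delong_compare(s, s, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  s2 <- s + rnorm(200)
  ab <- delong_compare(s, s2, y)
  ba <- delong_compare(s2, s, y)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$auc_a, auc(s, y), tolerance = 1e-12)
  expect_error(delong_compare(s, s2[-1], y), "length mismatch")
})

test_that("delong_compare agrees with an independent DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  x <- rnorm(400); y <- rbinom(400, 1, plogis(1.5 * x))
  a <- x + rnorm(400); b <- x + rnorm(400)
  ours <- delong_compare(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(ours$difference,
               unname(ref$estimate[1] - ref$estimate[2]), tolerance = 1e-12)
})

test_that("hosmer_lemeshow is zero under perfect calibration and matches hand arithmetic", {
  # two groups of 10, predictions equal to group event proportions
  p <- rep(c(0.2, 0.7), each = 10)
  y <- c(rep(1:0, c(2, 8)), rep(1:0, c(7, 3)))
  hl <- hosmer_lemeshow(p, y, n_groups = 2)
  expect_equal(hl$chi2, 0)
  expect_identical(hl$df, 0L)
  # hand-computed 2-group toy: O1=3,E1=2,O2=6,E2=7, n=10 each
  y2 <- c(rep(1:0, c(3, 7)), rep(1:0, c(6, 4)))
  hl2 <- hosmer_lemeshow(p, y2, n_groups = 2)
  hand <- (3 - 2)^2 / (10 * 0.2 * 0.8) + (6 - 7)^2 / (10 * 0.7 * 0.3)
  expect_equal(hl2$chi2, hand, tolerance = 1e-10)
  expect_equal(hl2$observed, c(3, 6))
  expect_equal(hl2$expected, c(2, 7))
  # expected counts bounded by group size
  expect_true(all(hl2$expected <= hl2$group_n))
  expect_error(hosmer_lemeshow(c(0, 0.5), 0:1), "strictly in")
})

test_that("operating_point handles perfect and degenerate scores and matches a sweep", {
  # survival-oriented: scores = 1 - outcome means every death scores 0
  y <- rep(c(1, 0), c(20, 80))
  op <- operating_point(1 - y, y, target_sensitivity = 0.95)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  opc <- operating_point(rep(5, 100), y)
  expect_equal(opc$sensitivity, 1)
  expect_equal(opc$specificity, 0)
  # brute-force sweep oracle on integer T-NTS scores
  set.seed(78)
  reg <- simulate_registry(default_cohort_spec(n = 5000, seed = 78),
                           missingness = FALSE)
  sp <- score_panel(reg)
  for (target in c(0.5, 0.8, 0.95)) {
    op <- operating_point(sp$t_nts, sp$died, target)
    best <- -Inf; best_thr <- NA
    for (t in c(3:23, Inf)) {
      sens <- mean(sp$t_nts[sp$died] < t)
      spec <- mean(sp$t_nts[!sp$died] >= t)
      if (sens >= target && spec > best) { best <- spec; best_thr <- t }
    }
    expect_equal(op$specificity, best)
    expect_equal(op$threshold, best_thr)
    expect_gte(op$sensitivity, target)
  }
})

test_that("binned_mortality aggregates correctly and flags empty bins", {
  y <- c(1, 0, 0, 1, 0)
  v <- c(5, 15, 25, 35, 45)
  one <- binned_mortality(v, y, c(0, 50))
  expect_equal(one$mortality, mean(y))
  bm <- binned_mortality(v, y, c(0, 10, 20, 30, 31, 50))
  expect_identical(bm$count, c(1L, 1L, 1L, 0L, 2L))
  expect_true(is.na(bm$mortality[4]))
  expect_equal(bm$mortality[1], 1)
  expect_error(binned_mortality(v, y, c(10, 50)), "outside")
  expect_error(binned_mortality(v, y, c(0, 0, 50)), "strictly increasing")
})

test_that("mortality against SBP is bimodal on the synthetic cohort", {
  reg <- simulate_registry(default_cohort_spec(n = 60000, seed = 79),
                           missingness = FALSE)
  bm <- binned_mortality(reg$sbp, reg$died, c(0, 70, 90, 110, 150, 400))
  # monotone decline into the normotensive band, then a hypertensive uptick
  expect_true(all(diff(bm$mortality[1:4]) < 0))
  expect_gt(bm$mortality[5], bm$mortality[4])
})

test_that("describe_cohort reports medians/IQRs and two-sided tests", {
  reg <- simulate_registry(default_cohort_spec(n = 1500, seed = 80),
                           missingness = FALSE)
  same <- describe_cohort(reg, reg)
  expect_true(all(same$p >= 0.99))
  # location shift of one SD is detected
  shifted <- reg
  shifted$sbp <- shifted$sbp + stats::sd(reg$sbp)
  cmp <- describe_cohort(reg, shifted)
  expect_lt(cmp$p[cmp$variable == "sbp"], 0.001)
  # median/IQR strings agree with a direct quantile oracle
  q <- stats::quantile(reg$sbp, c(0.25, 0.5, 0.75))
  expect_identical(cmp$summary_a[cmp$variable == "sbp"],
                   sprintf("%.4g (%.4g-%.4g)", q[2], q[1], q[3]))
})
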