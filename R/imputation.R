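#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing vitals and ISS by chained regressions with predictive mean
#' matching (PMM): each incomplete variable is regressed on the others (age,
#' sex and the in-hospital death outcome are always conditioned on), the
#' regression coefficients are perturbed by a draw from their sampling
#' distribution, and each missing cell receives the *observed* value of a
#' donor chosen uniformly among the `donor_k` observed cases whose predicted
#' means lie nearest the missing case's prediction. Imputed values are
#' therefore always real observed values (integer GCS stays integer, SpO2
#' stays in the observed range). The chain is run `iterations` times per
#' completed dataset and the whole procedure `m` times, giving `m` completed
#' registries whose observed cells are identical.
#'
#' Non-measurable SpO2 (`spo2_nm`) is informative, not missing at random: it
#' is never imputed, and enters predictor matrices as the clinical floor
#' value 0.
#'
#' @param registry A trauma registry data frame.
#' @param variables Variables eligible for imputation (those actually
#'   containing missing values are imputed).
#' @param m Number of completed datasets (default 10, chosen to reach the
#'   cohort's largest missingness percentage).
#' @param iterations Chained-equation cycles per dataset.
#' @param donor_k Size of the PMM donor pool.
#' @param seed Integer seed; the same seed reproduces the imputation
#'   bit-for-bit.
#' @return An object of class `imputation_set`: list with `datasets` (list of
#'   `m` completed registries), `m`, `iterations`, `donor_k`, `seed`,
#'   `variables` (those imputed).
#' @examples
#' reg <- simulate_registry(default_cohort_spec(n = 300, seed = 1))
#' imp <- mice_pmm(reg, m = 2, iterations = 3, seed = 9)
#' completed_registry(imp, 1)
#' @export
mice_pmm <- function(registry, variables = c("gcs", "sbp", "rr", "spo2", "iss"),
                     m = 10, iterations = 10, donor_k = 5, seed = 1) {
  stopifnot(is.data.frame(registry), nrow(registry) > 1, m >= 1,
            iterations >= 1, donor_k >= 1)
  variables <- intersect(variables, names(registry))
  nm <- if ("spo2_nm" %in% names(registry)) registry$spo2_nm else
    rep(FALSE, nrow(registry))
  miss <- lapply(variables, function(v) {
    mis <- is.na(registry[[v]])
    if (v == "spo2") mis <- mis & !nm
    mis
  })
  names(miss) <- variables
  targets <- variables[vapply(miss, any, logical(1))]
  for (v in targets)
    if (!any(!is.na(registry[[v]])))
      stop("variable '", v, "' has zero observed values")
  base <- registry
  if (any(nm)) base$spo2[nm] <- 0  # informative floor for use as a predictor
  predictor_cols <- function(exclude) {
    cols <- setdiff(unique(c("age", "sex", "died", variables)), exclude)
    intersect(cols, names(base))
  }
  as_num <- function(col, x) {
    if (col == "sex") return(as.numeric(x == "male"))
    if (is.logical(x)) return(as.numeric(x))
    as.numeric(x)
  }
  set.seed(as.integer(seed))
  datasets <- vector("list", m)
  for (j in seq_len(m)) {
    cur <- base
    for (v in targets)  # init: random draws from the observed values
      cur[[v]][miss[[v]]] <- sample(cur[[v]][!is.na(cur[[v]])],
                                    sum(miss[[v]]), replace = TRUE)
    for (it in seq_len(iterations)) {
      for (v in targets) {
        mis <- miss[[v]]
        obs <- !mis & !is.na(base[[v]])
        if (v == "spo2") obs <- obs & !nm  # NM cells are not donors
        pc <- predictor_cols(v)
        X <- cbind(1, vapply(pc, function(cn) as_num(cn, cur[[cn]]),
                             numeric(nrow(cur))))
        y <- as.numeric(cur[[v]])
        qr_o <- qr(X[obs, , drop = FALSE])
        keep <- qr_o$pivot[seq_len(qr_o$rank)]
        Xo <- X[obs, keep, drop = FALSE]
        beta <- qr.coef(qr(Xo), y[obs])
        res <- y[obs] - Xo %*% beta
        df_res <- max(sum(obs) - length(beta), 1)
        sigma2 <- sum(res^2) / stats::rchisq(1, df_res)
        XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-10, ncol(Xo))))
        beta_star <- beta + drop(t(chol(sigma2 * XtXinv + diag(1e-12, ncol(Xo)))) %*%
                                   stats::rnorm(length(beta)))
        yhat_obs <- drop(Xo %*% beta)
        yhat_mis <- drop(X[mis, keep, drop = FALSE] %*% beta_star)
        obs_idx <- which(obs)
        for (i in seq_along(yhat_mis)) {
          d <- abs(yhat_obs - yhat_mis[i])
          pool <- obs_idx[order(d)[seq_len(min(donor_k, length(d)))]]
          cur[[v]][which(mis)[i]] <- base[[v]][sample(pool, 1)]
        }
      }
    }
    if (any(nm)) cur$spo2[nm] <- NA  # restore the NM sentinel representation
    datasets[[j]] <- cur
  }
  structure(list(datasets = datasets, m = m, iterations = iterations,
                 donor_k = donor_k, seed = as.integer(seed),
                 variables = targets),
            class = "imputation_set")
}

#' @rdname mice_pmm
#' @param set An `imputation_set`.
#' @param i Index of the completed dataset, 1..m.
#' @export
completed_registry <- function(set, i) {
  stopifnot(inherits(set, "imputation_set"), i >= 1, i <= set$m)
  set$datasets[[i]]
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d, %d iterations, donor k = %d, seed %d\n",
              x$m, x$iterations, x$donor_k, x$seed))
  cat("  imputed variables:", if (length(x$variables))
    paste(x$variables, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Pool coefficients across imputations (Rubin's rules)
#'
#' Combines `m` per-imputation logistic fits: the pooled estimate is the mean
#' of the per-imputation estimates; the total variance is the mean
#' within-imputation variance plus `(1 + 1/m)` times the between-imputation
#' variance. Inference uses the t reference with the classical
#' degrees-of-freedom formula.
#'
#' @param models A list of `logistic_fit` objects sharing covariate names.
#' @return A data frame of class `pooled_fit` with columns `term`,
#'   `estimate`, `se`, `within_var`, `between_var`, `df`, `statistic`, `p`.
#' @export
pool_coefficients <- function(models) {
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, logical(1), "logistic_fit")))
  nms <- names(models[[1]]$coefficients)
  for (mod in models)
    if (!identical(names(mod$coefficients), nms))
      stop("models have mismatched covariate names")
  m <- length(models)
  Q <- vapply(models, function(f) f$coefficients, numeric(length(nms)))
  U <- vapply(models, function(f) f$se^2, numeric(length(nms)))
  if (length(nms) == 1) { Q <- matrix(Q, 1); U <- matrix(U, 1) }
  qbar <- rowMeans(Q)
  ubar <- rowMeans(U)
  B <- if (m > 1) apply(Q, 1, stats::var) else rep(0, length(nms))
  Tvar <- ubar + (1 + 1 / m) * B
  r <- (1 + 1 / m) * B / ubar
  df <- ifelse(B > 0 & m > 1, (m - 1) * (1 + 1 / r)^2, Inf)
  stat <- qbar / sqrt(Tvar)
  out <- data.frame(term = nms, estimate = qbar, se = sqrt(Tvar),
                    within_var = ubar, between_var = B, df = df,
                    statistic = stat,
                    p = 2 * stats::pt(-abs(stat), df), row.names = NULL)
  class(out) <- c("pooled_fit", "data.frame")
  out
}
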