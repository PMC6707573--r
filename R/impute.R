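# Intention-to-treat missing-data handling.
#
# Clinical outcomes (PSS and utility scores at T2/T3) get proper multiple
# imputation: per incomplete variable a Bayesian normal linear regression on
# baseline predictors, with posterior draws of the coefficients and residual
# variance, so imputations vary across the m completed copies. Cost
# aggregates get deterministic regression imputation (predicted values,
# floored at zero), computed per recall window and per cost category.

OUTCOME_VARS <- c("pss_t2", "pss_t3", "sf6d_t2", "sf6d_t3",
                  "eq5d_t2", "eq5d_t3")

#' Imputation configuration
#'
#' @param m Number of multiple imputations for clinical outcomes
#'   (default 10).
#' @param seed Integer seed.
#' @param predictors Baseline predictor columns used by both imputation
#'   models and the dropout model.
#' @return List of class `imputation_config`.
#' @export
imputation_config <- function(m = 10, seed = 1,
                              predictors = c("arm", "pss_t1", "sf6d_t1",
                                             "eq5d_t1", "wage_month")) {
  stopifnot(m >= 1)
  structure(list(m = m, seed = seed, predictors = predictors),
            class = "imputation_config")
}

# design matrix from predictor columns (arm becomes an indicator)
impute_design <- function(records, predictors) {
  cols <- lapply(predictors, function(p) {
    x <- records[[p]]
    if (p == "arm") as.numeric(x == "ISMI") else as.numeric(x)
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", predictors)
  if (anyNA(X)) {
    bad <- predictors[vapply(seq_along(predictors) + 1L,
                             function(j) anyNA(X[, j]), logical(1))]
    tc_stop("predictor column(s) with missing values: ",
            paste(bad, collapse = ", "))
  }
  X
}

# one posterior draw of (beta, sigma) from the normal linear model y ~ X
draw_norm_model <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) tc_stop("singular imputation design")
  beta_hat <- qr.coef(qr_x, y)
  res <- y - X %*% beta_hat
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qr_x)
  beta <- beta_hat + backsolve(R, stats::rnorm(ncol(X))) * sqrt(sigma2)
  list(beta = beta, sigma = sqrt(sigma2))
}

clamp_outcome <- function(x, var) {
  if (startsWith(var, "pss")) pmin(40, pmax(0, round(x)))
  else if (startsWith(var, "sf6d")) pmin(1, pmax(0, x))
  else pmin(1, pmax(-0.6, x))
}

#' Multiple imputation of clinical outcomes
#'
#' Produces `m` completed copies of the records. Observed values are never
#' altered; each missing T2/T3 outcome score is drawn from the posterior
#' predictive of a normal linear regression on the baseline predictors, so
#' imputed values differ across copies. Imputed PSS scores are rounded and
#' clamped to 0-40, utilities to their instrument ranges. Seed-deterministic.
#'
#' @param records Participant records.
#' @param config An [imputation_config()].
#' @return List of `m` completed data.frames.
#' @export
impute_outcomes <- function(records, config = imputation_config()) {
  set.seed(derive_seed(config$seed, "impute-outcomes"))
  X <- impute_design(records, config$predictors)
  out <- vector("list", config$m)
  for (k in seq_len(config$m)) {
    done <- records
    for (var in OUTCOME_VARS) {
      y <- records[[var]]
      mis <- is.na(y)
      if (!any(mis)) next
      if (all(mis)) tc_stop("no observed values to fit imputation model for ", var)
      fit <- draw_norm_model(X[!mis, , drop = FALSE], y[!mis])
      pred <- X[mis, , drop = FALSE] %*% fit$beta +
        stats::rnorm(sum(mis), 0, fit$sigma)
      done[[var]][mis] <- clamp_outcome(pred, var)
    }
    out[[k]] <- done
  }
  out
}

#' Regression imputation of window cost aggregates
#'
#' Completes missing per-window per-category costs (as produced by the
#' costing stage for participants whose follow-up recall window is missing)
#' with the predicted values from a linear regression on arm, the same
#' category's baseline-window cost, and the baseline predictors; predictions
#' are floored at zero. Deterministic: no noise is added. If the design is
#' singular the arm mean is imputed instead, with a warning.
#'
#' @param w1,w3 Window cost data.frames from the costing stage (columns
#'   `id`, `arm`, one per category); `w1` must be complete.
#' @param records Participant records (for the baseline predictors).
#' @param predictors Extra predictor columns (default baseline PSS, SF-6D
#'   and wage).
#' @return List with completed `w1` and `w3`.
#' @export
impute_costs <- function(w1, w3, records,
                         predictors = c("pss_t1", "sf6d_t1", "wage_month")) {
  cats <- setdiff(names(w3), c("id", "arm"))
  if (anyNA(w1[cats])) tc_stop("baseline window costs must be complete")
  base <- impute_design(records, c("arm", predictors))
  for (cat in cats) {
    y <- w3[[cat]]
    mis <- is.na(y)
    if (!any(mis)) next
    X <- cbind(base, w1[[cat]])
    # drop predictors that are constant among the observed rows (e.g. a
    # baseline cost column that is all zero) before judging singularity
    keep <- c(TRUE, vapply(2:ncol(X), function(j) {
      stats::sd(X[!mis, j]) > 0
    }, logical(1)))
    X <- X[, keep, drop = FALSE]
    qr_x <- qr(X[!mis, , drop = FALSE])
    if (qr_x$rank < ncol(X)) {
      tc_warn("singular design for ", cat, ": imputing arm means")
      for (a in unique(w3$arm)) {
        sel <- mis & w3$arm == a
        y[sel] <- mean(y[w3$arm == a & !mis])
      }
    } else {
      beta <- qr.coef(qr_x, y[!mis])
      y[mis] <- X[mis, , drop = FALSE] %*% beta
    }
    w3[[cat]] <- pmax(0, y)
  }
  list(w1 = w1, w3 = w3)
}

#' Logistic model of study dropout
#'
#' Fits `dropout ~ predictors` by logistic regression, for reporting which
#' baseline characteristics predict loss to follow-up (not for weighting).
#' Complete separation is detected and flagged.
#'
#' @param records Participant records with a logical `dropout` column.
#' @param predictors Predictor columns (default arm, baseline PSS, baseline
#'   SF-6D, wage).
#' @return List with `coefficients`, `se`, `z`, `separation` (logical flag)
#'   and the fitted `model`.
#' @export
dropout_model <- function(records,
                          predictors = c("arm", "pss_t1", "sf6d_t1",
                                         "wage_month")) {
  y <- records$dropout
  if (is.null(y)) y <- is.na(records$pss_t3)
  if (all(y) || !any(y)) {
    tc_stop("dropout model needs at least one dropout and one completer")
  }
  dat <- records[predictors]
  dat$.dropout <- as.numeric(y)
  fit <- suppressWarnings(
    stats::glm(.dropout ~ ., data = dat, family = stats::binomial()))
  p <- stats::fitted(fit)
  separation <- any(p < 1e-8 | p > 1 - 1e-8)
  sm <- summary(fit)$coefficients
  list(coefficients = sm[, "Estimate"], se = sm[, "Std. Error"],
       z = sm[, "z value"], separation = separation, model = fit)
}
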