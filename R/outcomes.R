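# Clinical and utility outcomes: symptom-free remission on the PSS-10,
# QALYs by trapezoidal area under the utility curve, and the descriptive
# effect statistics of a two-arm trial.

#' Outcome configuration
#'
#' Holds the symptom-free threshold definition (baseline sample mean minus a
#' multiple of the baseline SD) and the assessment timepoints.
#'
#' @param baseline_mean Baseline PSS-10 sample mean (default 25.52).
#' @param baseline_sd Baseline PSS-10 sample SD (default 3.91).
#' @param sd_multiplier SDs below the mean defining remission (default 2).
#' @param tp Timepoints, see [timepoints()].
#' @return List of class `outcome_config` with the derived `threshold`
#'   (default 25.52 - 2 * 3.91 = 17.70).
#' @export
outcome_config <- function(baseline_mean = 25.52, baseline_sd = 3.91,
                           sd_multiplier = 2, tp = timepoints()) {
  stopifnot(sd_multiplier > 0, baseline_sd > 0)
  threshold <- baseline_mean - sd_multiplier * baseline_sd
  if (!is.finite(threshold)) tc_stop("symptom-free threshold is not finite")
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 sd_multiplier = sd_multiplier, threshold = threshold,
                 timepoints = tp),
            class = "outcome_config")
}

#' Symptom-free status at follow-up
#'
#' A participant is symptom-free when the follow-up PSS-10 score lies below
#' the baseline sample mean minus two baseline SDs (strict inequality;
#' immaterial for integer scores since the default threshold 17.70 is not an
#' integer).
#'
#' @param pss_t3 Follow-up PSS-10 score(s); must be complete
#'   (post-imputation).
#' @param config An [outcome_config()].
#' @return Logical vector.
#' @export
symptom_free <- function(pss_t3, config = outcome_config()) {
  if (anyNA(pss_t3)) tc_stop("missing follow-up PSS score: impute first")
  pss_t3 < config$threshold
}

#' QALYs by trapezoidal area under the utility curve
#'
#' Utilities at the three assessments (weeks 0, 7, 26) are linearly
#' interpolated and integrated; weeks convert to years at exactly 52
#' weeks/year, so constant full health over the horizon yields 0.5 QALYs.
#' No baseline adjustment is applied.
#'
#' @param utilities Numeric vector of length 3 `(u_t1, u_t2, u_t3)`, or an
#'   n-by-3 matrix/data.frame for many participants. Must be complete.
#' @param tp Timepoints, see [timepoints()].
#' @return QALYs in years (scalar or vector).
#' @export
qaly_auc <- function(utilities, tp = timepoints()) {
  u <- if (is.null(dim(utilities))) matrix(utilities, nrow = 1)
       else as.matrix(utilities)
  if (ncol(u) != 3) tc_stop("utilities must have one value per timepoint")
  if (anyNA(u)) tc_stop("missing utility: impute first")
  w <- tp$weeks
  area <- (u[, 1] + u[, 2]) / 2 * (w[["t2"]] - w[["t1"]]) +
    (u[, 2] + u[, 3]) / 2 * (w[["t3"]] - w[["t2"]])
  q <- area / 52
  if (is.null(dim(utilities))) q[[1]] else unname(q)
}

#' Number needed to treat
#'
#' Reciprocal of the risk difference between arms.
#'
#' @param p_treat,p_control Response proportions in `[0, 1]`.
#' @return NNT (persons); negative values indicate harm.
#' @export
nnt <- function(p_treat, p_control) {
  stopifnot(p_treat >= 0, p_treat <= 1, p_control >= 0, p_control <= 1)
  if (p_treat == p_control) {
    tc_stop("risk difference is zero: NNT undefined")
  }
  1 / (p_treat - p_control)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic without continuity correction, 1 df, for comparing a
#' binary outcome between two arms. Cells are `(a, b)` = events/non-events
#' in the first arm and `(c, d)` in the second.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return List with `statistic`, `df` (1) and `p_value`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) tc_stop("zero margin: chi-square undefined")
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Mean PSS change in one arm
#'
#' Arithmetic mean and SD of the pre-minus-post change (improvement is
#' positive) for the participants of one arm; scores must be complete
#' (post-imputation, intention-to-treat).
#'
#' @param records Participant records.
#' @param arm Arm label (`"ISMI"` or `"WLC"`).
#' @param from,to Timepoint column suffixes (default `t1` to `t3`).
#' @return List with `mean`, `sd`, `n`.
#' @export
mean_change <- function(records, arm, from = "t1", to = "t3") {
  sel <- records$arm == arm
  if (!any(sel)) tc_stop("no participants in arm ", arm)
  pre <- records[[paste0("pss_", from)]][sel]
  post <- records[[paste0("pss_", to)]][sel]
  if (anyNA(pre) || anyNA(post)) tc_stop("missing PSS scores: impute first")
  change <- pre - post
  list(mean = mean(change), sd = stats::sd(change), n = sum(sel))
}

# effect columns for the decision analysis, from one completed dataset
effect_values <- function(records, effect_kind, config = outcome_config()) {
  switch(effect_kind,
    pss = records$pss_t1 - records$pss_t3,
    symptomfree = as.numeric(symptom_free(records$pss_t3, config)),
    qaly = qaly_auc(records[c("sf6d_t1", "sf6d_t2", "sf6d_t3")],
                    config$timepoints),
    qaly_eq5d = qaly_auc(records[c("eq5d_t1", "eq5d_t2", "eq5d_t3")],
                         config$timepoints),
    tc_stop("unknown effect kind: ", effect_kind)
  )
}
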