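# Decision-analytic core: bootstrapped seemingly-unrelated-regression
# incremental costs and effects, ICER with dominance semantics,
# cost-effectiveness plane quadrant distribution, and acceptability curves
# by net-monetary-benefit counting.

#' Seemingly unrelated regression of cost and effect on arm
#'
#' Jointly summarises the cost and effect equations, both regressed on an
#' intercept and the arm indicator. With identical regressors in the two
#' equations, the SUR point estimates coincide with equation-by-equation
#' least squares, i.e. the arm-mean differences; the cross-equation residual
#' correlation is reported alongside.
#'
#' @param dataset Data.frame with columns `arm`, `cost`, `effect`.
#' @return List with `delta_cost`, `delta_effect` (ISMI minus WLC),
#'   `residual_cor` (NA when residuals are degenerate) and `n`.
#' @export
fit_sur <- function(dataset) {
  if (length(unique(dataset$arm)) < 2) {
    tc_stop("both arms are required to estimate incremental quantities")
  }
  x <- as.numeric(dataset$arm == "ISMI")
  fit_c <- stats::lm.fit(cbind(1, x), dataset$cost)
  fit_e <- stats::lm.fit(cbind(1, x), dataset$effect)
  rc <- fit_c$residuals
  re <- fit_e$residuals
  tol <- sqrt(.Machine$double.eps)
  degen <- stats::sd(rc) <= tol * (1 + max(abs(dataset$cost))) ||
    stats::sd(re) <= tol * (1 + max(abs(dataset$effect)))
  rho <- if (degen) NA_real_ else stats::cor(rc, re)
  list(delta_cost = unname(fit_c$coefficients[2]),
       delta_effect = unname(fit_e$coefficients[2]),
       residual_cor = rho, n = nrow(dataset))
}

#' Bootstrap the incremental cost-effect cloud
#'
#' Nonparametric bootstrap of the SUR incremental estimates: each draw
#' resamples participants with replacement within arm (stratified, so the
#' per-arm sample sizes are preserved) and recomputes the incremental cost
#' and effect. Draws are stacked equally across the `m` completed datasets
#' from multiple imputation; the point estimates are the across-imputation
#' means of the per-dataset estimates (Rubin's mean rule). Seed-determinate.
#'
#' @param datasets A data.frame with columns `arm`, `cost`, `effect`, or a
#'   list of such data.frames (one per completed imputation).
#' @param B Number of bootstrap draws (default 5000).
#' @param seed Integer seed.
#' @param effect_kind Label recorded on the cloud (e.g. `"symptomfree"`,
#'   `"qaly"`, `"pss"`).
#' @return Object of class `icer_cloud`: data.frame with columns
#'   `delta_effect`, `delta_cost` and attributes `delta_cost_hat`,
#'   `delta_effect_hat`, `effect_kind`, `B`, `seed`.
#' @export
bootstrap_cloud <- function(datasets, B = 5000, seed = 1,
                            effect_kind = "effect") {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  m <- length(datasets)
  stopifnot(B >= 1, m >= 1)
  point <- lapply(datasets, fit_sur)
  dc_hat <- mean(vapply(point, `[[`, 0, "delta_cost"))
  de_hat <- mean(vapply(point, `[[`, 0, "delta_effect"))

  set.seed(seed)
  dc <- de <- numeric(B)
  idx_arm <- lapply(datasets, function(d) {
    list(i1 = which(d$arm == "ISMI"), i0 = which(d$arm == "WLC"))
  })
  for (b in seq_len(B)) {
    k <- ((b - 1L) %% m) + 1L          # stack draws equally over imputations
    d <- datasets[[k]]
    ia <- idx_arm[[k]]
    s1 <- sample(ia$i1, length(ia$i1), replace = TRUE)
    s0 <- sample(ia$i0, length(ia$i0), replace = TRUE)
    dc[b] <- mean(d$cost[s1]) - mean(d$cost[s0])
    de[b] <- mean(d$effect[s1]) - mean(d$effect[s0])
  }
  structure(data.frame(delta_effect = de, delta_cost = dc),
            delta_cost_hat = dc_hat, delta_effect_hat = de_hat,
            effect_kind = effect_kind, B = B, seed = seed,
            class = c("icer_cloud", "data.frame"))
}

#' Incremental cost-effectiveness ratio with dominance semantics
#'
#' Computes `delta_cost / delta_effect`, replacing meaningless negative
#' ratios with dominance labels: more health at lower cost is `"dominant"`,
#' less health at higher cost is `"dominated"`. A zero effect difference
#' leaves the ratio undefined.
#'
#' @param delta_cost,delta_effect Incremental cost (EUR) and effect.
#' @return List of class `trialcea_icer` with `value` (numeric or NA) and
#'   `label` (`"ratio"`, `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
icer <- function(delta_cost, delta_effect) {
  out <- if (delta_effect == 0) {
    list(value = NA_real_, label = "undefined")
  } else if (delta_effect > 0 && delta_cost < 0) {
    list(value = NA_real_, label = "dominant")
  } else if (delta_effect < 0 && delta_cost > 0) {
    list(value = NA_real_, label = "dominated")
  } else {
    list(value = delta_cost / delta_effect, label = "ratio")
  }
  structure(c(out, list(delta_cost = delta_cost, delta_effect = delta_effect)),
            class = "trialcea_icer")
}

#' @export
print.trialcea_icer <- function(x, ...) {
  lab <- switch(x$label,
                ratio = sprintf("%.2f per effect unit", x$value),
                dominant = "Dominant (more effect, lower cost)",
                dominated = "Dominated (less effect, higher cost)",
                undefined = "Undefined (zero effect difference)")
  cat("ICER:", lab, "\n")
  invisible(x)
}

#' Quadrant distribution on the cost-effectiveness plane
#'
#' Percentage of bootstrap draws per quadrant, by the signs of the
#' incremental effect (east = positive) and incremental cost (north =
#' positive). Draws with an exactly zero effect difference are assigned to
#' the east (positive-effect) side, zero cost differences to the south side,
#' so every draw is counted exactly once and the percentages sum to 100.
#'
#' @param cloud An `icer_cloud`.
#' @return Named numeric (`NE`, `SE`, `SW`, `NW`), percentages.
#' @export
plane_distribution <- function(cloud) {
  east <- cloud$delta_effect >= 0
  north <- cloud$delta_cost > 0
  counts <- c(NE = sum(east & north), SE = sum(east & !north),
              SW = sum(!east & !north), NW = sum(!east & north))
  100 * counts / nrow(cloud)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay ceiling, the probability of the intervention
#' being cost-effective is the fraction of bootstrap draws with positive net
#' monetary benefit `lambda * delta_effect - delta_cost`.
#'
#' @param cloud An `icer_cloud`.
#' @param wtp_grid Strictly increasing, nonnegative WTP grid (EUR per effect
#'   unit).
#' @return Data.frame of class `ceac_curve` with columns `wtp`,
#'   `probability`.
#' @export
ceac <- function(cloud, wtp_grid) {
  stopifnot(all(is.finite(wtp_grid)), all(wtp_grid >= 0),
            !is.unsorted(wtp_grid, strictly = TRUE))
  prob <- vapply(wtp_grid, function(lambda) {
    mean(lambda * cloud$delta_effect - cloud$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            effect_kind = attr(cloud, "effect_kind"),
            class = c("ceac_curve", "data.frame"))
}

#' Percentile bootstrap confidence intervals
#'
#' 2.5th/97.5th percentiles (for `level = 0.95`) of the incremental cost and
#' effect draws, plus the ICER uncertainty summary in the reporting
#' convention for ratios spanning quadrants: when the lower end of the cloud
#' lies in the dominant (south-east) quadrant the lower limit is the label
#' `"dominant"` and the upper limit is the 97.5th percentile of the ratio
#' among north-east draws ("dominant to X").
#'
#' @param cloud An `icer_cloud`.
#' @param level Confidence level (default 0.95).
#' @return List with `cost` and `effect` (length-2 numeric), and
#'   `icer_range` (list with `lower`, `upper`, possibly character labels).
#' @export
percentile_ci <- function(cloud, level = 0.95) {
  if (nrow(cloud) < 20) tc_warn("fewer than 20 draws: percentile interval unstable")
  alpha <- (1 - level) / 2
  pr <- c(alpha, 1 - alpha)
  ci_cost <- unname(stats::quantile(cloud$delta_cost, pr, type = 7))
  ci_eff <- unname(stats::quantile(cloud$delta_effect, pr, type = 7))
  se <- cloud$delta_effect > 0 & cloud$delta_cost < 0
  ne <- cloud$delta_effect > 0 & cloud$delta_cost > 0
  icer_range <- if (mean(se) >= alpha && any(ne)) {
    ratios <- cloud$delta_cost[ne] / cloud$delta_effect[ne]
    list(lower = "dominant",
         upper = unname(stats::quantile(ratios, 1 - alpha, type = 7)))
  } else {
    ratios <- ifelse(cloud$delta_effect != 0,
                     cloud$delta_cost / cloud$delta_effect, NA_real_)
    qs <- stats::quantile(ratios, pr, na.rm = TRUE, type = 7)
    list(lower = unname(qs[1]), upper = unname(qs[2]))
  }
  list(cost = ci_cost, effect = ci_eff, icer_range = icer_range)
}

#' Default willingness-to-pay grids
#'
#' 0-5000 EUR in steps of 100 per symptom-free person, 0-50,000 in steps of
#' 500 per QALY, 0-1000 in steps of 20 per PSS point.
#'
#' @return Named list of numeric grids (`pss`, `symptomfree`, `qaly`).
#' @export
default_wtp_grids <- function() {
  list(pss = seq(0, 1000, by = 20),
       symptomfree = seq(0, 5000, by = 100),
       qaly = seq(0, 50000, by = 500))
}
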