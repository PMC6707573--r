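# Synthetic two-arm trial generator.
#
# Emulates a 1:1 randomized trial of a guided internet-based stress-management
# intervention (ISMI) versus waitlist control (WLC): elevated baseline
# perceived stress (PSS-10 truncated at the inclusion cutoff), arm-specific
# stress improvement, SF-6D/EQ-5D utilities negatively coupled to concurrent
# stress, right-skewed zero-inflated resource-use costs over two 3-month
# recall windows, rare high inpatient episodes, and arm-specific dropout.

# zero-inflated positive-part parameters per category, arm and (implicitly)
# window; mean_units is the UNCONDITIONAL mean so closed-form moments are
# available via expected_summaries()
default_cost_params <- function() {
  p <- function(category, ismi, wlc, p_zero, sdlog,
                p_zero_wlc = p_zero) {
    data.frame(category = category,
               arm = c("ISMI", "WLC"),
               mean_units = c(ismi, wlc),
               p_zero = c(p_zero, p_zero_wlc),
               sdlog = sdlog,
               stringsAsFactors = FALSE)
  }
  rbind(
    p("physician_contacts",     2.04,  2.27, 0.35, 0.7),
    p("specialist_contacts",    0.57,  0.63, 0.60, 0.7),
    p("psychological_contacts", 0.69,  1.31, 0.75, 0.8),
    p("allied_contacts",        3.34,  3.48, 0.55, 0.9),
    p("semiresidential_days",   0.47,  0.15, 0.970, 0.6, p_zero_wlc = 0.985),
    p("rehabilitation_days",    0.033, 0.37, 0.995, 0.5, p_zero_wlc = 0.970),
    p("otc_eur",               24.0,  24.0,  0.50, 1.0),
    p("car_km",                36.0,  65.0,  0.40, 0.9),
    p("public_transport_eur",   2.7,   4.9,  0.80, 0.8),
    p("waiting_hours",         10.5,  11.4,  0.25, 0.8),
    p("informal_care_hours",   11.6,  18.1,  0.60, 1.1),
    p("absence_days",           4.57,  5.62, 0.50, 1.0),
    p("impaired_days",         18.8,  20.9,  0.30, 0.7)
  )
}

#' Configuration of the synthetic trial generator
#'
#' Builds the generator configuration with defaults matching the emulated
#' trial design: 132 participants per arm, baseline PSS-10 drawn from a
#' normal with mean 25.52 and SD 3.91 truncated below at the inclusion
#' cutoff 22, PSS improvement to follow-up of 9.75 (ISMI) versus 3.0 (WLC)
#' points with common SD 6, SF-6D baseline utility 0.65 (SD 0.11 ISMI /
#' 0.08 WLC), an inpatient admission probability of 0.034, and dropout
#' probabilities 0.128 (ISMI) / 0.0833 (WLC). Cost categories are
#' zero-inflated lognormal (gamma selectable) in natural resource units,
#' calibrated loosely to the published per-arm cost levels.
#'
#' @param n_per_arm Participants per arm (default 132).
#' @param ... Named overrides for any configuration field; see Details.
#'
#' @details Overridable fields include `baseline_pss_mean`,
#' `baseline_pss_sd`, `inclusion_cutoff`, `improvement_mean` (named vector
#' ISMI/WLC), `improvement_sd`, `t2_noise_sd`, `sf6d_baseline_mean`,
#' `sf6d_sd`, `sf6d_gain_t2`, `sf6d_gain_t3`, `eq5d_baseline_mean`,
#' `eq5d_sd`, `eq5d_gain_t2`, `eq5d_gain_t3`, `pss_utility_cor`,
#' `cost_params` (data.frame as in the default), `inpatient_admission_prob`,
#' `inpatient_mean_days`, `inpatient_days_sdlog`, `rx_prob`, `rx_max_items`,
#' `wage_median`, `wage_sdlog`, `workdays_per_month`, `dropout_prob`,
#' `inefficiency_shape`, `positive_family` ("lognormal" or "gamma").
#' The SF-6D trajectory gains default to a between-arm utility gap of 0.015
#' at week 7 and 0.02 at week 26, i.e. a configured QALY difference of
#' about 0.0074 over the half-year horizon.
#'
#' @return An object of class `trial_generator_config`.
#' @export
generator_config <- function(n_per_arm = 132, ...) {
  cfg <- list(
    n_per_arm = n_per_arm,
    baseline_pss_mean = 25.52,
    baseline_pss_sd = 3.91,
    inclusion_cutoff = 22,
    improvement_mean = c(ISMI = 9.75, WLC = 3.0),
    improvement_sd = 6,
    t2_noise_sd = 3,
    sf6d_baseline_mean = 0.65,
    sf6d_sd = c(ISMI = 0.11, WLC = 0.08),
    sf6d_gain_t2 = c(ISMI = 0.065, WLC = 0.050),
    sf6d_gain_t3 = c(ISMI = 0.120, WLC = 0.100),
    eq5d_baseline_mean = 0.55,
    eq5d_sd = c(ISMI = 0.10, WLC = 0.10),
    eq5d_gain_t2 = c(ISMI = 0.014, WLC = 0.010),
    eq5d_gain_t3 = c(ISMI = 0.025, WLC = 0.020),
    pss_utility_cor = -0.4,
    cost_params = default_cost_params(),
    inpatient_admission_prob = 0.034,
    inpatient_mean_days = 14,
    inpatient_days_sdlog = 0.6,
    rx_prob = 0.25,
    rx_max_items = 2,
    wage_median = 3000,
    wage_sdlog = 0.35,
    workdays_per_month = 260 / 12,
    dropout_prob = c(ISMI = 0.128, WLC = 0.0833),
    inefficiency_shape = c(2, 5),
    positive_family = "lognormal"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) tc_stop("unknown generator field(s): ",
                               paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$n_per_arm < 2) tc_stop("n_per_arm must be at least 2")
  if (cfg$baseline_pss_sd <= 0 || cfg$improvement_sd <= 0) {
    tc_stop("standard deviations must be positive")
  }
  probs <- c(cfg$dropout_prob, cfg$inpatient_admission_prob, cfg$rx_prob,
             cfg$cost_params$p_zero)
  if (any(probs < 0 | probs > 1)) tc_stop("probabilities must lie in [0,1]")
  if (!cfg$positive_family %in% c("lognormal", "gamma")) {
    tc_stop("positive_family must be 'lognormal' or 'gamma'")
  }
  class(cfg) <- "trial_generator_config"
  cfg
}

# draw positive parts with mean m_cond and lognormal-equivalent spread
draw_positive <- function(n, m_cond, sdlog, family) {
  if (n == 0) return(numeric(0))
  if (family == "lognormal") {
    stats::rlnorm(n, meanlog = log(m_cond) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    cv2 <- exp(sdlog^2) - 1   # matched coefficient of variation
    shape <- 1 / cv2
    stats::rgamma(n, shape = shape, rate = shape / m_cond)
  }
}

draw_zi <- function(n, mean_units, p_zero, sdlog, family) {
  pos <- stats::runif(n) >= p_zero
  out <- numeric(n)
  if (mean_units > 0 && p_zero < 1) {
    out[pos] <- draw_positive(sum(pos), mean_units / (1 - p_zero), sdlog, family)
  }
  out
}

#' Generate a synthetic two-arm trial dataset
#'
#' Draws a complete wide dataset per [trial_schema()], then applies dropout:
#' for sampled participants the post-treatment and follow-up outcome scores
#' and the entire follow-up recall window are deleted (empty cells).
#' Identical `(config, seed)` pairs give identical datasets.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for all randomness.
#' @return A validated data.frame of participant records (with `dropout`).
#' @export
generate_trial <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "trial_generator_config"))
  set.seed(seed)
  n <- 2L * config$n_per_arm
  arm <- rep(ARMS, each = config$n_per_arm)
  id <- sprintf("P%04d", seq_len(n))

  # baseline PSS: normal truncated below at the inclusion cutoff
  lo <- stats::pnorm(config$inclusion_cutoff, config$baseline_pss_mean,
                     config$baseline_pss_sd)
  if (lo >= 1) tc_stop("degenerate config: truncation mass is empty")
  pss1_raw <- stats::qnorm(stats::runif(n, lo, 1),
                           config$baseline_pss_mean, config$baseline_pss_sd)
  pss_t1 <- pmin(40, round(pss1_raw))

  improvement <- stats::rnorm(n, config$improvement_mean[arm],
                              config$improvement_sd)
  pss3_raw <- pmin(40, pmax(0, pss1_raw - improvement))
  pss_t3 <- round(pss3_raw)
  pss2_raw <- pmin(40, pmax(0, pss1_raw - improvement * 7 / 26 +
                              stats::rnorm(n, 0, config$t2_noise_sd)))
  pss_t2 <- round(pss2_raw)

  # utilities: Gaussian copula coupling to concurrent stress, standardised
  # within arm so the coupling shapes the joint distribution without moving
  # the configured arm-level utility means
  rho <- abs(config$pss_utility_cor)
  util <- function(mu, sd_arm, pss_raw) {
    z <- numeric(n)
    for (a in ARMS) {
      sel <- arm == a
      z[sel] <- (pss_raw[sel] - mean(pss_raw[sel])) / stats::sd(pss_raw[sel])
    }
    eps <- stats::rnorm(n)
    mu + sd_arm * (-rho * z + sqrt(1 - rho^2) * eps)
  }
  sf6d_t1 <- pmin(1, pmax(0, util(config$sf6d_baseline_mean,
                                  config$sf6d_sd[arm], pss1_raw)))
  sf6d_t2 <- pmin(1, pmax(0, util(config$sf6d_baseline_mean +
                                    config$sf6d_gain_t2[arm],
                                  config$sf6d_sd[arm], pss2_raw)))
  sf6d_t3 <- pmin(1, pmax(0, util(config$sf6d_baseline_mean +
                                    config$sf6d_gain_t3[arm],
                                  config$sf6d_sd[arm], pss3_raw)))
  eq5d_t1 <- pmin(1, pmax(-0.6, util(config$eq5d_baseline_mean,
                                     config$eq5d_sd[arm], pss1_raw)))
  eq5d_t2 <- pmin(1, pmax(-0.6, util(config$eq5d_baseline_mean +
                                       config$eq5d_gain_t2[arm],
                                     config$eq5d_sd[arm], pss2_raw)))
  eq5d_t3 <- pmin(1, pmax(-0.6, util(config$eq5d_baseline_mean +
                                       config$eq5d_gain_t3[arm],
                                     config$eq5d_sd[arm], pss3_raw)))

  wage_month <- stats::rlnorm(n, log(config$wage_median), config$wage_sdlog)

  df <- data.frame(id = id, arm = arm,
                   pss_t1 = pss_t1, pss_t2 = pss_t2, pss_t3 = pss_t3,
                   sf6d_t1 = sf6d_t1, sf6d_t2 = sf6d_t2, sf6d_t3 = sf6d_t3,
                   eq5d_t1 = eq5d_t1, eq5d_t2 = eq5d_t2, eq5d_t3 = eq5d_t3,
                   wage_month = wage_month, stringsAsFactors = FALSE)

  # resource-use windows: stationary category parameters, drawn per window
  cp <- config$cost_params
  for (w in c("w1", "w3")) {
    for (cat in unique(cp$category)) {
      x <- numeric(n)
      for (a in ARMS) {
        row <- cp[cp$category == cat & cp$arm == a, ]
        sel <- arm == a
        x[sel] <- draw_zi(sum(sel), row$mean_units, row$p_zero, row$sdlog,
                          config$positive_family)
      }
      df[[paste0(cat, "_", w)]] <- x
    }
    df[[paste0("inefficiency_", w)]] <- stats::rbeta(
      n, config$inefficiency_shape[1], config$inefficiency_shape[2])
    # prescriptions: compact 'drug:packages;...' encoding
    has_rx <- stats::runif(n) < config$rx_prob
    n_items <- ifelse(has_rx, sample(config$rx_max_items, n, replace = TRUE), 0)
    drugs <- paste0("D0", 1:6)
    rx <- character(n)
    for (i in which(n_items > 0)) {
      items <- sample(drugs, n_items[i])
      pkgs <- sample(2, n_items[i], replace = TRUE)
      rx[i] <- paste(paste0(items, ":", pkgs), collapse = ";")
    }
    rx[rx == ""] <- NA_character_
    df[[paste0("rx_items_", w)]] <- rx
  }

  # rare high-cost inpatient episodes, assigned to one window
  admitted <- stats::runif(n) < config$inpatient_admission_prob
  in_w1 <- stats::runif(n) < 0.5
  days <- pmin(92, draw_positive(n, config$inpatient_mean_days,
                                 config$inpatient_days_sdlog,
                                 config$positive_family))
  df$inpatient_days_w1 <- ifelse(admitted & in_w1, days, 0)
  df$inpatient_days_w3 <- ifelse(admitted & !in_w1, days, 0)

  # dropout: delete post-treatment/follow-up outcomes and the whole W_T3 window
  drop <- stats::runif(n) < config$dropout_prob[arm]
  out_cols <- c("pss_t2", "pss_t3", "sf6d_t2", "sf6d_t3", "eq5d_t2", "eq5d_t3")
  for (col in out_cols) df[[col]][drop] <- NA
  for (col in resource_columns("w3")) df[[col]][drop] <- NA

  df <- df[trial_schema()$column]
  validate_trial(df, strict = TRUE, inclusion_cutoff = config$inclusion_cutoff)
  df$dropout <- is.na(df$pss_t3)
  df
}

#' Closed-form moments of the generator
#'
#' Analytic expectations implied by a generator configuration, for
#' parameter-recovery testing: per-arm mean PSS improvement, per-arm QALY
#' (from the configured SF-6D trajectory, clamping ignored), per-category
#' expected per-window and 6-month costs, and the configured incremental
#' 6-month cost (ISMI minus WLC, including the one-off intervention tariff).
#'
#' @param config A [generator_config()].
#' @param unit_costs A `unit_cost_table` (default packaged table).
#' @param drug_prices A `drug_price_table` (default packaged formulary).
#' @return List with `pss_improvement`, `qaly_sf6d`, `delta_qaly_sf6d`,
#'   `window_cost` (data.frame category x arm), `six_month_cost`,
#'   `total_six_month`, `delta_cost`.
#' @export
expected_summaries <- function(config = generator_config(),
                               unit_costs = default_unit_costs(),
                               drug_prices = read_drug_prices()) {
  stopifnot(inherits(config, "trial_generator_config"))
  price_of <- c(
    physician_contacts = unit_price(unit_costs, "physician_contact"),
    specialist_contacts = unit_price(unit_costs, "specialist_contact"),
    psychological_contacts = unit_price(unit_costs, "psychological_contact"),
    allied_contacts = unit_price(unit_costs, "allied_health_contact"),
    semiresidential_days = unit_price(unit_costs, "semiresidential_day"),
    rehabilitation_days = unit_price(unit_costs, "rehabilitation_day"),
    otc_eur = 1,
    car_km = unit_price(unit_costs, "car_km"),
    public_transport_eur = 1,
    waiting_hours = unit_price(unit_costs, "opportunity_hour"),
    informal_care_hours = unit_price(unit_costs, "informal_care_hour")
  )
  mean_wage <- config$wage_median * exp(config$wage_sdlog^2 / 2)
  daily_wage <- mean_wage / config$workdays_per_month
  beta_mean <- config$inefficiency_shape[1] / sum(config$inefficiency_shape)

  cp <- config$cost_params
  rows <- lapply(ARMS, function(a) {
    cpa <- cp[cp$arm == a, ]
    cpa$mean_units[cpa$p_zero >= 1] <- 0   # fully inflated category
    m <- stats::setNames(cpa$mean_units, cpa$category)
    cost <- c(
      physician_services = m[["physician_contacts"]] * price_of[["physician_contacts"]] +
        m[["specialist_contacts"]] * price_of[["specialist_contacts"]],
      psychological_services = m[["psychological_contacts"]] *
        price_of[["psychological_contacts"]],
      inpatient = config$inpatient_admission_prob * 0.5 *
        config$inpatient_mean_days * unit_price(unit_costs, "inpatient_day"),
      semiresidential = m[["semiresidential_days"]] * price_of[["semiresidential_days"]],
      rehabilitation = m[["rehabilitation_days"]] * price_of[["rehabilitation_days"]],
      nonphysician_services = m[["allied_contacts"]] * price_of[["allied_contacts"]],
      prescription = config$rx_prob *
        mean(seq_len(config$rx_max_items)) *   # expected items
        1.5 *                                  # expected packages per item
        mean(weighted_drug_prices(drug_prices,
                                  statutory_share(unit_costs))$price),
      otc = m[["otc_eur"]],
      opportunity = m[["waiting_hours"]] * price_of[["waiting_hours"]],
      travel = m[["car_km"]] * price_of[["car_km"]] + m[["public_transport_eur"]],
      informal_care = m[["informal_care_hours"]] * price_of[["informal_care_hours"]],
      absenteeism = m[["absence_days"]] * daily_wage,
      presenteeism = m[["impaired_days"]] * beta_mean * daily_wage
    )
    data.frame(category = names(cost), arm = a, window_mean_eur = unname(cost),
               stringsAsFactors = FALSE)
  })
  window_cost <- do.call(rbind, rows)
  six <- window_cost
  names(six)[3] <- "six_month_mean_eur"
  six$six_month_mean_eur <- six$six_month_mean_eur * 2   # two stationary windows
  interv <- data.frame(category = "intervention", arm = ARMS,
                       six_month_mean_eur =
                         c(unit_price(unit_costs, "intervention"), 0),
                       stringsAsFactors = FALSE)
  six <- rbind(interv, six)
  totals <- tapply(six$six_month_mean_eur, six$arm, sum)

  # configured QALYs from the utility trajectory (week 0/7/26, 52-week year)
  qaly <- sapply(ARMS, function(a) {
    mu <- config$sf6d_baseline_mean +
      c(0, config$sf6d_gain_t2[[a]], config$sf6d_gain_t3[[a]])
    ((mu[1] + mu[2]) / 2 * 7 + (mu[2] + mu[3]) / 2 * 19) / 52
  })

  list(
    pss_improvement = config$improvement_mean,
    qaly_sf6d = qaly,
    delta_qaly_sf6d = unname(qaly["ISMI"] - qaly["WLC"]),
    window_cost = window_cost,
    six_month_cost = six,
    total_six_month = totals,
    delta_cost = unname(totals[["ISMI"]] - totals[["WLC"]])
  )
}
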