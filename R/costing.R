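# Societal-perspective costing of self-reported resource use, 2013 EUR.
#
# Per-category costs are unit counts times standard unit prices; productivity
# losses use the human-capital approach (absenteeism) and lost-workday
# equivalents from an inefficiency score (presenteeism). Window costs are
# cumulated to the 6-month horizon by linear interpolation between the two
# 3-month recall windows (trapezoid); the intervention tariff is a one-off.

COST_CATEGORIES <- c(
  "intervention", "physician_services", "psychological_services", "inpatient",
  "semiresidential", "rehabilitation", "nonphysician_services", "prescription",
  "otc", "opportunity", "travel", "informal_care",
  "absenteeism", "presenteeism"
)

COST_GROUPS <- list(
  health_care = c("intervention", "physician_services",
                  "psychological_services", "inpatient", "semiresidential",
                  "rehabilitation", "nonphysician_services", "prescription"),
  patient_family = c("otc", "opportunity", "travel", "informal_care"),
  productivity = c("absenteeism", "presenteeism")
)

statutory_share <- function(unit_costs) unit_price(unit_costs, "statutory_share")

#' Health-care service costs for one recall window
#'
#' Multiplies per-category service units by their standard unit prices.
#'
#' @param window Named list or one-row data.frame with fields
#'   `physician_contacts`, `specialist_contacts`, `psychological_contacts`,
#'   `allied_contacts`, `inpatient_days`, `semiresidential_days`,
#'   `rehabilitation_days`.
#' @param unit_costs A `unit_cost_table`.
#' @return Named numeric: EUR per health-care category (`physician_services`
#'   combines GP and specialist contacts).
#' @export
service_costs <- function(window, unit_costs) {
  need <- c("physician_contacts", "specialist_contacts",
            "psychological_contacts", "allied_contacts", "inpatient_days",
            "semiresidential_days", "rehabilitation_days")
  miss <- setdiff(need, names(window))
  if (length(miss) > 0) tc_stop("window lacks field(s): ",
                                paste(miss, collapse = ", "))
  u <- function(f) as.numeric(window[[f]])
  c(
    physician_services = u("physician_contacts") *
      unit_price(unit_costs, "physician_contact") +
      u("specialist_contacts") * unit_price(unit_costs, "specialist_contact"),
    psychological_services = u("psychological_contacts") *
      unit_price(unit_costs, "psychological_contact"),
    inpatient = u("inpatient_days") * unit_price(unit_costs, "inpatient_day"),
    semiresidential = u("semiresidential_days") *
      unit_price(unit_costs, "semiresidential_day"),
    rehabilitation = u("rehabilitation_days") *
      unit_price(unit_costs, "rehabilitation_day"),
    nonphysician_services = u("allied_contacts") *
      unit_price(unit_costs, "allied_health_contact")
  )
}

# parse "D01:2;D03:1" into data.frame(drug, packages)
parse_rx <- function(x) {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    return(data.frame(drug = character(0), packages = numeric(0)))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) tc_stop("malformed prescription entry: '", x, "'")
  data.frame(drug = vapply(parts, `[`, "", 1),
             packages = as.numeric(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

# per-drug weighted package price: mean over the up-to-3 largest packages of
# the statutory and private retail prices, weighted by the statutory share
weighted_drug_prices <- function(drug_prices, share) {
  out <- lapply(split(drug_prices, drug_prices$drug), function(d) {
    d <- d[order(-d$package_size), ]
    d <- d[seq_len(min(3, nrow(d))), ]
    share * mean(d$statutory_price_eur) + (1 - share) * mean(d$private_price_eur)
  })
  data.frame(drug = names(out), price = unname(unlist(out)),
             stringsAsFactors = FALSE)
}

#' Prescription medication costs
#'
#' Per drug, the package price is the mean over the up-to-3 largest packages,
#' computed separately for statutory and private insurance and combined as
#' `share * statutory + (1 - share) * private` with the statutory population
#' share (default 0.888). Cost is packages dispensed times that price.
#'
#' @param prescriptions Either a compact string `"drug:packages;..."`, or a
#'   data.frame with columns `drug` and `packages`. `NA`/empty means none.
#' @param drug_prices A `drug_price_table` (see [read_drug_prices()]).
#' @param share Statutory population share in `[0, 1]` (default 0.888).
#' @return Total cost in EUR.
#' @export
medication_costs <- function(prescriptions, drug_prices = read_drug_prices(),
                             share = 0.888) {
  if (is.character(prescriptions) || (length(prescriptions) == 1 &&
                                      is.na(prescriptions))) {
    prescriptions <- parse_rx(as.character(prescriptions))
  }
  if (nrow(prescriptions) == 0) return(0)
  wp <- weighted_drug_prices(drug_prices, share)
  idx <- match(prescriptions$drug, wp$drug)
  if (anyNA(idx)) {
    tc_stop("unknown drug id: ",
            paste(prescriptions$drug[is.na(idx)], collapse = ", "))
  }
  sum(prescriptions$packages * wp$price[idx])
}

#' Travel costs to reach health services
#'
#' Car trips are valued per kilometre (default rate 0.30 EUR/km); bus and
#' taxi trips at their reported fare.
#'
#' @param trips Data.frame with columns `mode` (`car`, `bus`, `taxi`), `km`
#'   (round-trip kilometres, car only) and `fare` (EUR, bus/taxi only).
#' @param unit_costs A `unit_cost_table`.
#' @return Total travel cost in EUR.
#' @export
travel_costs <- function(trips, unit_costs = default_unit_costs()) {
  if (nrow(trips) == 0) return(0)
  car <- trips$mode == "car"
  if (any(car & is.na(trips$km))) tc_stop("car trip without kilometres")
  sum(trips$km[car]) * unit_price(unit_costs, "car_km") +
    sum(trips$fare[!car], na.rm = FALSE)
}

#' Opportunity cost of waiting and treatment time
#'
#' Leisure time spent waiting for or receiving treatment, valued at the
#' opportunity rate (default 23.10 EUR/h). Time spent on the intervention
#' itself is treated as leisure and not valued.
#'
#' @param hours Nonnegative hours.
#' @param unit_costs A `unit_cost_table`.
#' @return Cost in EUR.
#' @export
opportunity_costs <- function(hours, unit_costs = default_unit_costs()) {
  stopifnot(all(hours >= 0, na.rm = TRUE))
  hours * unit_price(unit_costs, "opportunity_hour")
}

#' Informal care and domestic help costs
#'
#' Substitution method: unpaid care hours valued at the market wage of a
#' professional substitute (default 18.33 EUR/h).
#'
#' @inheritParams opportunity_costs
#' @export
informal_care_costs <- function(hours, unit_costs = default_unit_costs()) {
  stopifnot(all(hours >= 0, na.rm = TRUE))
  hours * unit_price(unit_costs, "informal_care_hour")
}

#' Absenteeism cost (human capital approach)
#'
#' Work-loss days times the participant's average gross daily wage, derived
#' from the monthly salary.
#'
#' @param absence_days Work-loss days.
#' @param gross_monthly_wage Gross monthly wage, EUR.
#' @param workdays_per_month Divisor for the daily wage (default 260/12).
#' @return Cost in EUR.
#' @export
absenteeism_cost <- function(absence_days, gross_monthly_wage,
                             workdays_per_month = 260 / 12) {
  stopifnot(workdays_per_month > 0)
  absence_days * gross_monthly_wage / workdays_per_month
}

#' Presenteeism cost (lost-workday equivalents)
#'
#' Reduced-efficiency workdays times the inefficiency score give lost-workday
#' equivalents, valued at the gross daily wage.
#'
#' @param impaired_days Workdays attended at reduced efficiency.
#' @param inefficiency_score Efficiency loss in `[0, 1]` (a raw 0-10 scale
#'   must be divided by 10 at ingest).
#' @inheritParams absenteeism_cost
#' @return Cost in EUR.
#' @export
presenteeism_cost <- function(impaired_days, inefficiency_score,
                              gross_monthly_wage,
                              workdays_per_month = 260 / 12) {
  stopifnot(all(inefficiency_score >= 0 & inefficiency_score <= 1, na.rm = TRUE))
  impaired_days * inefficiency_score * gross_monthly_wage / workdays_per_month
}

#' Intervention cost
#'
#' The flat per-participant tariff (default 299 EUR) for the intervention
#' arm; 0 for waitlist control.
#'
#' @param arm Character vector of arm labels (`ISMI`/`WLC`).
#' @param unit_costs A `unit_cost_table`.
#' @param offset Additive price offset for sensitivity analyses (e.g. +100).
#' @return Cost in EUR per participant.
#' @export
intervention_cost <- function(arm, unit_costs = default_unit_costs(),
                              offset = 0) {
  ifelse(arm == "ISMI", unit_price(unit_costs, "intervention") + offset, 0)
}

#' Cumulate two 3-month window costs to the 6-month horizon
#'
#' Area-under-the-curve linear interpolation between the two 3-month cost
#' rates: the trapezoid `(w1 + w3) / 2 * horizon/3`, which with a 6-month
#' horizon equals `w1 + w3`. The alternative of projecting the follow-up
#' window alone is available via `method = "double_followup"`.
#'
#' @param cost_w1 Baseline-window cost(s), EUR.
#' @param cost_w3 Follow-up-window cost(s), EUR.
#' @param horizon_months Horizon in months (default 6).
#' @param method `"trapezoid"` (default) or `"double_followup"`.
#' @return 6-month cost(s), EUR.
#' @export
cumulate_auc <- function(cost_w1, cost_w3, horizon_months = 6,
                         method = c("trapezoid", "double_followup")) {
  method <- match.arg(method)
  if (anyNA(cost_w1) || anyNA(cost_w3)) {
    tc_stop("missing window cost: run cost imputation first")
  }
  if (method == "trapezoid") {
    (cost_w1 + cost_w3) / 2 * horizon_months / 3
  } else {
    cost_w3 * horizon_months / 3
  }
}

#' Price indexation and currency conversion
#'
#' Indexes an amount to the 2013 reference year and converts to US dollars
#' at the OECD purchasing power parity (1 EUR = 1.29 USD in 2013).
#'
#' @param amount Amount in source-year EUR.
#' @param index_factor Consumer-price index factor to the reference year
#'   (default 1, i.e. the amount is already in 2013 EUR; 1.04 indexes 2010
#'   prices).
#' @param ppp USD per EUR (default 1.29).
#' @return List with `eur` (indexed) and `usd`.
#' @export
price_adjust <- function(amount, index_factor = 1, ppp = 1.29) {
  eur <- amount * index_factor
  list(eur = eur, usd = eur * ppp)
}

# per-participant category costs for one recall window; all-NA windows
# (dropout) yield NA in every category
window_costs <- function(records, window, unit_costs = default_unit_costs(),
                         drug_prices = read_drug_prices(),
                         workdays_per_month = 260 / 12) {
  g <- function(stem) records[[paste0(stem, "_", window)]]
  n <- nrow(records)
  svc <- data.frame(
    physician_services = g("physician_contacts") *
      unit_price(unit_costs, "physician_contact") +
      g("specialist_contacts") * unit_price(unit_costs, "specialist_contact"),
    psychological_services = g("psychological_contacts") *
      unit_price(unit_costs, "psychological_contact"),
    inpatient = g("inpatient_days") * unit_price(unit_costs, "inpatient_day"),
    semiresidential = g("semiresidential_days") *
      unit_price(unit_costs, "semiresidential_day"),
    rehabilitation = g("rehabilitation_days") *
      unit_price(unit_costs, "rehabilitation_day"),
    nonphysician_services = g("allied_contacts") *
      unit_price(unit_costs, "allied_health_contact")
  )
  share <- statutory_share(unit_costs)
  wp <- weighted_drug_prices(drug_prices, share)
  rx_col <- g("rx_items")
  # a missing window leaves every numeric field NA; an empty rx cell in an
  # observed window means "no prescriptions"
  window_missing <- is.na(g("otc_eur"))
  rx <- vapply(seq_len(n), function(i) {
    if (window_missing[i]) return(NA_real_)
    items <- parse_rx(rx_col[i])
    if (nrow(items) == 0) return(0)
    idx <- match(items$drug, wp$drug)
    if (anyNA(idx)) tc_stop("row ", records$id[i], ": unknown drug id ",
                            paste(items$drug[is.na(idx)], collapse = ", "))
    sum(items$packages * wp$price[idx])
  }, numeric(1))
  out <- cbind(
    data.frame(id = records$id, arm = records$arm, stringsAsFactors = FALSE),
    svc,
    prescription = rx,
    otc = g("otc_eur"),
    opportunity = g("waiting_hours") * unit_price(unit_costs, "opportunity_hour"),
    travel = g("car_km") * unit_price(unit_costs, "car_km") +
      g("public_transport_eur"),
    informal_care = g("informal_care_hours") *
      unit_price(unit_costs, "informal_care_hour"),
    absenteeism = absenteeism_cost(g("absence_days"), records$wage_month,
                                   workdays_per_month),
    presenteeism = presenteeism_cost(g("impaired_days"), g("inefficiency"),
                                     records$wage_month, workdays_per_month)
  )
  out
}

#' Per-participant cost breakdown over the 6-month horizon
#'
#' Applies every category costing operation to both recall windows, cumulates
#' to 6 months via [cumulate_auc()], and adds the one-off intervention tariff
#' to the intervention arm. Both windows must be complete (impute first; see
#' [impute_costs()]).
#'
#' @param records Participant records (wide data.frame).
#' @param unit_costs A `unit_cost_table`.
#' @param drug_prices A `drug_price_table`.
#' @param options List of scenario options: `exclude_inpatient` (logical,
#'   drop inpatient costs), `intervention_offset` (EUR added to the tariff),
#'   `auc_method` (`"trapezoid"`/`"double_followup"`),
#'   `workdays_per_month`, `usd` (also report USD totals).
#' @return Object of class `cost_breakdown`: list with `per_window` (long
#'   data.frame), `six_month` (wide per-participant data.frame with category
#'   columns, group totals and `total`), and `options`.
#' @export
cost_breakdown <- function(records, unit_costs = default_unit_costs(),
                           drug_prices = read_drug_prices(),
                           options = list()) {
  opt <- utils::modifyList(
    list(exclude_inpatient = FALSE, intervention_offset = 0,
         auc_method = "trapezoid", workdays_per_month = 260 / 12,
         usd = FALSE), options)
  w1 <- window_costs(records, "w1", unit_costs, drug_prices,
                     opt$workdays_per_month)
  w3 <- window_costs(records, "w3", unit_costs, drug_prices,
                     opt$workdays_per_month)
  cumulate_windows(records, w1, w3, unit_costs, opt)
}

# shared by cost_breakdown() and the pipeline (which imputes between the
# window computation and the cumulation)
cumulate_windows <- function(records, w1, w3, unit_costs, opt) {
  cats <- setdiff(COST_CATEGORIES, "intervention")
  if (isTRUE(opt$exclude_inpatient)) {
    w1$inpatient <- ifelse(is.na(w1$inpatient), NA, 0)
    w3$inpatient <- ifelse(is.na(w3$inpatient), NA, 0)
  }
  six <- data.frame(id = records$id, arm = records$arm,
                    stringsAsFactors = FALSE)
  six$intervention <- intervention_cost(records$arm, unit_costs,
                                        offset = opt$intervention_offset)
  for (cat in cats) {
    six[[cat]] <- cumulate_auc(w1[[cat]], w3[[cat]], 6, opt$auc_method)
  }
  for (grp in names(COST_GROUPS)) {
    six[[grp]] <- rowSums(six[COST_GROUPS[[grp]]])
  }
  six$total <- rowSums(six[COST_CATEGORIES])
  if (isTRUE(opt$usd)) {
    six$total_usd <- price_adjust(six$total)$usd
  }
  per_window <- rbind(cbind(window = "w1", w1), cbind(window = "w3", w3))
  structure(list(per_window = per_window, six_month = six, options = opt),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("6-month societal cost breakdown:", nrow(x$six_month), "participants\n")
  means <- tapply(x$six_month$total, x$six_month$arm, mean)
  for (a in names(means)) {
    cat(sprintf("  mean total (%s): %.0f EUR\n", a, means[[a]]))
  }
  invisible(x)
}
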