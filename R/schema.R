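# Column schema for wide (one row per participant) trial datasets.
#
# Two 3-month recall windows are carried: `w1` covers the three months before
# baseline (T1) and `w3` the three months before the 6-month follow-up (T3).
# Outcome scores are indexed t1 (week 0), t2 (week 7), t3 (week 26).

ARMS <- c("ISMI", "WLC")

# resource-use stems repeated per recall window
RESOURCE_STEMS <- c(
  "physician_contacts", "specialist_contacts", "psychological_contacts",
  "allied_contacts", "inpatient_days", "semiresidential_days",
  "rehabilitation_days", "rx_items", "otc_eur", "car_km",
  "public_transport_eur", "waiting_hours", "informal_care_hours",
  "absence_days", "impaired_days", "inefficiency"
)

resource_columns <- function(window) paste0(RESOURCE_STEMS, "_", window)

#' Column schema for wide trial datasets
#'
#' Returns the schema used by [read_trial()] and [write_trial()]: one row per
#' column with its type, whether it is mandatory, and the validation range.
#' The same schema is shipped as `inst/extdata/trial_schema.csv`.
#'
#' @return A data.frame with columns `column`, `type`, `required`, `min`,
#'   `max`, `description`.
#' @export
trial_schema <- function() {
  num <- function(col, min = 0, max = Inf, desc = "") {
    data.frame(column = col, type = "numeric", required = TRUE,
               min = min, max = max, description = desc,
               stringsAsFactors = FALSE)
  }
  base <- rbind(
    data.frame(column = "id", type = "character", required = TRUE,
               min = NA, max = NA, description = "participant identifier",
               stringsAsFactors = FALSE),
    data.frame(column = "arm", type = "character", required = TRUE,
               min = NA, max = NA,
               description = "trial arm: ISMI (intervention) or WLC (waitlist)",
               stringsAsFactors = FALSE),
    num("pss_t1", 0, 40, "PSS-10 at baseline (week 0), integer"),
    num("pss_t2", 0, 40, "PSS-10 post-treatment (week 7), integer"),
    num("pss_t3", 0, 40, "PSS-10 at 6-month follow-up (week 26), integer"),
    num("sf6d_t1", 0, 1, "SF-6D utility at T1"),
    num("sf6d_t2", 0, 1, "SF-6D utility at T2"),
    num("sf6d_t3", 0, 1, "SF-6D utility at T3"),
    num("eq5d_t1", -0.6, 1, "EQ-5D-3L utility at T1 (may be negative)"),
    num("eq5d_t2", -0.6, 1, "EQ-5D-3L utility at T2"),
    num("eq5d_t3", -0.6, 1, "EQ-5D-3L utility at T3"),
    num("wage_month", 0, Inf, "gross monthly wage, EUR")
  )
  res <- do.call(rbind, lapply(c("w1", "w3"), function(w) {
    rbind(
      num(paste0("physician_contacts_", w), 0, Inf, "GP contacts in window"),
      num(paste0("specialist_contacts_", w), 0, Inf, "medical specialist contacts"),
      num(paste0("psychological_contacts_", w), 0, Inf,
          "psychiatrist/psychotherapist contacts"),
      num(paste0("allied_contacts_", w), 0, Inf,
          "allied-health contacts (physio, massage, OT)"),
      num(paste0("inpatient_days_", w), 0, 92, "hospital inpatient days"),
      num(paste0("semiresidential_days_", w), 0, Inf, "semiresidential care days"),
      num(paste0("rehabilitation_days_", w), 0, Inf, "rehabilitation days"),
      data.frame(column = paste0("rx_items_", w), type = "character",
                 required = TRUE, min = NA, max = NA,
                 description = "prescriptions as 'drug:packages;...' or empty",
                 stringsAsFactors = FALSE),
      num(paste0("otc_eur_", w), 0, Inf, "out-of-pocket OTC spend, EUR"),
      num(paste0("car_km_", w), 0, Inf, "round-trip car km to services"),
      num(paste0("public_transport_eur_", w), 0, Inf, "bus/taxi fares, EUR"),
      num(paste0("waiting_hours_", w), 0, Inf, "waiting/treatment hours"),
      num(paste0("informal_care_hours_", w), 0, Inf,
          "informal care / domestic help hours"),
      num(paste0("absence_days_", w), 0, Inf, "work-loss days"),
      num(paste0("impaired_days_", w), 0, Inf, "reduced-efficiency workdays"),
      num(paste0("inefficiency_", w), 0, 1, "inefficiency score in [0,1]")
    )
  }))
  rbind(base, res)
}

#' Assessment timepoints of the trial design
#'
#' Weeks of the three assessments (baseline, post-treatment, 6-month
#' follow-up) and the analysis horizon in years. A 52-week year is used, so
#' week 26 is exactly half a year.
#'
#' @return List with `weeks` (named numeric, length 3) and `horizon_years`.
#' @export
timepoints <- function() {
  list(weeks = c(t1 = 0, t2 = 7, t3 = 26), horizon_years = 26 / 52)
}
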