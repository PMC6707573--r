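test_that("service costs are units times unit price per category", {
  uc <- unit_costs_with(physician_contact = 20)
  w <- list(physician_contacts = 3, specialist_contacts = 0,
            psychological_contacts = 0, allied_contacts = 0,
            inpatient_days = 0, semiresidential_days = 0,
            rehabilitation_days = 0)
  expect_equal(unname(service_costs(w, uc)[["physician_services"]]), 60)

  w$physician_contacts <- 0
  expect_equal(unname(service_costs(w, uc)), rep(0, 6))

  w$inpatient_days <- 2
  expect_equal(unname(service_costs(w, unit_costs_with(inpatient_day = 550))[["inpatient"]]),
               1100)
  expect_error(service_costs(list(physician_contacts = 1), uc), "lacks")
})

test_that("medication costs weight statutory and private package prices", {
  # equal prices make the statutory share irrelevant
  expect_equal(medication_costs(data.frame(drug = "DX", packages = 1),
                                tiny_drug_prices(10, 10)), 10)
  # hand-computed weighted mean: 0.888 * 10 + 0.112 * 20 = 11.12
  expect_equal(medication_costs(data.frame(drug = "DX", packages = 1),
                                tiny_drug_prices(10, 20)), 11.12)
  expect_equal(medication_costs(data.frame(drug = character(0),
                                           packages = numeric(0)),
                                tiny_drug_prices(10, 20)), 0)
  expect_equal(medication_costs(NA_character_, tiny_drug_prices(10, 20)), 0)
  expect_error(medication_costs(data.frame(drug = "DY", packages = 1),
                                tiny_drug_prices(10, 20)), "DY")
})

test_that("only the 3 largest packages enter the mean package price", {
  dp <- tiny_drug_prices(statutory = c(1, 2, 3, 1000),
                         private = c(1, 2, 3, 1000),
                         sizes = c(100, 50, 20, 5))
  # largest three by size: prices 1, 2, 3 -> mean 2
  expect_equal(medication_costs(data.frame(drug = "DX", packages = 2), dp), 4)
  expect_equal(medication_costs("DX:2", dp), 4)   # compact string form
})

test_that("travel costs value car km at 0.30 and pass fares through", {
  uc <- default_unit_costs()
  expect_equal(travel_costs(data.frame(mode = "car", km = 20, fare = NA), uc), 6)
  expect_equal(travel_costs(data.frame(mode = "taxi", km = NA, fare = 15), uc), 15)
  expect_equal(travel_costs(data.frame(mode = character(0), km = numeric(0),
                                       fare = numeric(0)), uc), 0)
  expect_error(travel_costs(data.frame(mode = "car", km = NA, fare = 5), uc),
               "kilometres")
})

test_that("time costs use the standard hourly rates", {
  expect_equal(opportunity_costs(2), 46.20)
  expect_equal(opportunity_costs(0), 0)
  expect_equal(opportunity_costs(1.5), 34.65)
  expect_equal(informal_care_costs(3), 54.99)
  expect_equal(informal_care_costs(10), 183.30)
})

test_that("productivity losses follow the human-capital and Osterhaus rules", {
  expect_equal(absenteeism_cost(5, 3250, 21.67), 5 * 3250 / 21.67)
  expect_equal(round(absenteeism_cost(5, 3250, 21.67), 2), 749.88)
  expect_equal(absenteeism_cost(0, 3250), 0)
  # a full month of absence costs about the monthly wage
  expect_equal(absenteeism_cost(21.67, 3250, 21.67), 3250)

  expect_equal(presenteeism_cost(10, 0.3, 100 * 21.67, 21.67), 300)
  expect_equal(presenteeism_cost(50, 0, 3000), 0)
  expect_equal(presenteeism_cost(7, 1, 2900, 21.67),
               absenteeism_cost(7, 2900, 21.67))
})

test_that("the intervention tariff applies to the intervention arm only", {
  expect_equal(intervention_cost(c("ISMI", "WLC")), c(299, 0))
  expect_equal(intervention_cost("ISMI", unit_costs_with(intervention = 199)),
               199)
  expect_equal(intervention_cost(c("ISMI", "WLC"), offset = 100), c(399, 0))
})

test_that("window costs cumulate to 6 months by linear interpolation", {
  expect_equal(cumulate_auc(100, 300), 400)
  expect_equal(cumulate_auc(250, 250), 500)
  expect_equal(cumulate_auc(0, 0), 0)
  expect_equal(cumulate_auc(100, 300, method = "double_followup"), 600)
  expect_error(cumulate_auc(NA, 300), "imputation")
  # linearity per category
  a1 <- c(10, 20); a3 <- c(30, 0); b1 <- c(5, 5); b3 <- c(1, 2)
  expect_equal(cumulate_auc(a1 + b1, a3 + b3),
               cumulate_auc(a1, a3) + cumulate_auc(b1, b3))
})

test_that("price indexation and PPP conversion reproduce the printed dollars", {
  expect_equal(round(price_adjust(299)$usd), 386)
  expect_equal(price_adjust(50, index_factor = 1)$eur, 50)
  expect_equal(price_adjust(100, index_factor = 1.04)$eur, 104)
})

test_that("all-zero resource use costs exactly the intervention tariff", {
  recs <- make_records(blank_record("P1", "ISMI"), blank_record("P2", "WLC"))
  b <- cost_breakdown(recs)
  expect_equal(b$six_month$total, c(299, 0))
  expect_equal(b$six_month$health_care, c(299, 0))
  expect_equal(b$six_month$patient_family, c(0, 0))
})

test_that("excluding inpatient care removes exactly that category", {
  rec <- blank_record("P1", "ISMI", inpatient_days_w1 = 4, inpatient_days_w3 = 2)
  b0 <- cost_breakdown(make_records(rec))
  b1 <- cost_breakdown(make_records(rec), options = list(exclude_inpatient = TRUE))
  expect_equal(b0$six_month$inpatient, 6 * 550)
  expect_equal(b1$six_month$inpatient, 0)
  expect_equal(b1$six_month$health_care, b1$six_month$intervention)
})

test_that("cost breakdown is additive over categories and groups", {
  recs <- small_trial(n_per_arm = 30, seed = 21,
                      dropout_prob = c(ISMI = 0, WLC = 0))
  b <- cost_breakdown(recs)
  six <- b$six_month
  cats <- trialcea:::COST_CATEGORIES
  grps <- names(trialcea:::COST_GROUPS)
  expect_equal(six$total, rowSums(six[cats]), tolerance = 1e-9)
  expect_equal(six$total, rowSums(six[grps]), tolerance = 1e-9)
  for (g in grps) {
    expect_equal(six[[g]], rowSums(six[trialcea:::COST_GROUPS[[g]]]),
                 tolerance = 1e-9)
  }
})

test_that("costs are homogeneous of degree one in the unit prices", {
  recs <- small_trial(n_per_arm = 15, seed = 33,
                      dropout_prob = c(ISMI = 0, WLC = 0))
  uc <- default_unit_costs()
  uc2 <- uc
  scale_cats <- setdiff(uc$category,
                        c("price_index_factor", "ppp_eur_usd", "statutory_share"))
  uc2$unit_price_eur[uc2$category %in% scale_cats] <-
    2 * uc2$unit_price_eur[uc2$category %in% scale_cats]
  b1 <- cost_breakdown(recs, unit_costs = uc)$six_month
  b2 <- cost_breakdown(recs, unit_costs = uc2)$six_month
  priced <- c("intervention", "physician_services", "psychological_services",
              "inpatient", "semiresidential", "rehabilitation",
              "nonphysician_services", "opportunity", "informal_care")
  for (cat in priced) expect_equal(b2[[cat]], 2 * b1[[cat]], tolerance = 1e-9)
  # wage-derived productivity costs and pass-through spend do not scale
  expect_equal(b2$absenteeism, b1$absenteeism)
  expect_equal(b2$presenteeism, b1$presenteeism)
  expect_equal(b2$otc, b1$otc)
})
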