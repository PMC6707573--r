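# Fixtures built in code: hand-sized participant records and small
# configurations reused across the suite.

# one fully observed record with all resource use zero unless overridden
blank_record <- function(id = "P1", arm = "ISMI", pss = c(30, 25, 20),
                         sf6d = c(0.65, 0.7, 0.75), eq5d = c(0.6, 0.6, 0.65),
                         wage = 3000, ...) {
  rec <- list(id = id, arm = arm,
              pss_t1 = pss[1], pss_t2 = pss[2], pss_t3 = pss[3],
              sf6d_t1 = sf6d[1], sf6d_t2 = sf6d[2], sf6d_t3 = sf6d[3],
              eq5d_t1 = eq5d[1], eq5d_t2 = eq5d[2], eq5d_t3 = eq5d[3],
              wage_month = wage)
  for (col in c(trialcea:::resource_columns("w1"),
                trialcea:::resource_columns("w3"))) {
    rec[[col]] <- if (startsWith(col, "rx_items")) NA_character_ else 0
  }
  over <- list(...)
  stopifnot(all(names(over) %in% names(rec)))
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  recs <- do.call(rbind, list(...))
  recs$dropout <- is.na(recs$pss_t3)
  recs
}

# a pair of arm-constant records per arm with given total-ish cost knobs
two_arm_constant <- function(cost_ismi, cost_wlc, eff_ismi, eff_wlc,
                             n_per_arm = 2) {
  data.frame(
    arm = rep(c("ISMI", "WLC"), each = n_per_arm),
    cost = rep(c(cost_ismi, cost_wlc), each = n_per_arm),
    effect = rep(c(eff_ismi, eff_wlc), each = n_per_arm),
    stringsAsFactors = FALSE
  )
}

small_trial <- function(n_per_arm = 40, seed = 42, ...) {
  generate_trial(generator_config(n_per_arm = n_per_arm, ...), seed = seed)
}

# unit-cost table with a chosen price for one category
unit_costs_with <- function(...) {
  uc <- default_unit_costs()
  over <- list(...)
  for (cat in names(over)) uc$unit_price_eur[uc$category == cat] <- over[[cat]]
  uc
}

tiny_drug_prices <- function(statutory, private, sizes = 10) {
  structure(data.frame(drug = "DX", package_size = sizes,
                       statutory_price_eur = statutory,
                       private_price_eur = private,
                       stringsAsFactors = FALSE),
            class = c("drug_price_table", "data.frame"))
}
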