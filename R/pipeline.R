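# End-to-end orchestration: read/generate -> impute -> cost -> outcomes ->
# bootstrapped decision analysis per scenario, with Table-1/Table-2-shaped
# reporting.

SCENARIOS <- c("main", "no_inpatient", "intervention_plus_100",
               "intervention_minus_100", "eq5d")

scenario_costing_options <- function(scenario) {
  switch(scenario,
    main = list(),
    eq5d = list(),
    no_inpatient = list(exclude_inpatient = TRUE),
    intervention_plus_100 = list(intervention_offset = 100),
    intervention_minus_100 = list(intervention_offset = -100),
    tc_stop("unknown scenario: ", scenario)
  )
}

scenario_effects <- function(scenario) {
  if (scenario == "eq5d") "qaly_eq5d" else c("pss", "symptomfree", "qaly")
}

# completed analysis datasets: per imputed copy, a (arm, cost, effect) frame
analysis_datasets <- function(imputed, six_month, effect_kind,
                              config = outcome_config()) {
  lapply(imputed, function(rec) {
    data.frame(arm = rec$arm,
               cost = six_month$total,
               effect = effect_values(rec, effect_kind, config),
               stringsAsFactors = FALSE)
  })
}

#' Run one analysis scenario end to end
#'
#' Imputes outcomes and costs, builds the 6-month societal cost per
#' participant under the scenario's costing options, and runs the
#' bootstrapped SUR decision analysis for each of the scenario's effect
#' measures. Scenarios: `main`, `no_inpatient` (inpatient costs removed),
#' `intervention_plus_100` / `intervention_minus_100` (tariff shifted by
#' 100 EUR), `eq5d` (QALYs from the EQ-5D-3L instead of the SF-6D).
#'
#' Imputation and bootstrap seeds are derived from `seed` and the stage (and
#' effect) label only, never from the scenario, so scenarios share bootstrap
#' resampling indices and a flat tariff offset propagates exactly into the
#' incremental cost of every draw.
#'
#' @param records Participant records (wide data.frame).
#' @param scenario One of the scenario names above.
#' @param unit_costs A `unit_cost_table`.
#' @param drug_prices A `drug_price_table`.
#' @param B Bootstrap draws (default 5000).
#' @param m Outcome imputations (default 10).
#' @param seed Top-level integer seed.
#' @param wtp_grids Named list of WTP grids (see [default_wtp_grids()]).
#' @param outcome_cfg An [outcome_config()].
#' @param keep_cloud Keep the per-draw clouds in the result (default TRUE).
#' @return List of class `scenario_result`: per effect kind the point
#'   estimates, percentile CIs, ICER, plane distribution and CEAC; plus the
#'   cost breakdown object.
#' @export
run_scenario <- function(records, scenario = "main",
                         unit_costs = default_unit_costs(),
                         drug_prices = read_drug_prices(),
                         B = 5000, m = 10, seed = 1,
                         wtp_grids = default_wtp_grids(),
                         outcome_cfg = outcome_config(),
                         keep_cloud = TRUE) {
  scenario <- match.arg(scenario, SCENARIOS)
  opt <- utils::modifyList(
    list(exclude_inpatient = FALSE, intervention_offset = 0,
         auc_method = "trapezoid", workdays_per_month = 260 / 12,
         usd = FALSE),
    scenario_costing_options(scenario))

  if (scenario == "eq5d" && anyNA(records$eq5d_t1)) {
    tc_stop("eq5d scenario requested but EQ-5D baseline scores are missing")
  }

  imputed <- impute_outcomes(records,
                             imputation_config(m = m, seed = seed))
  w1 <- window_costs(records, "w1", unit_costs, drug_prices,
                     opt$workdays_per_month)
  w3 <- window_costs(records, "w3", unit_costs, drug_prices,
                     opt$workdays_per_month)
  if (isTRUE(opt$exclude_inpatient)) {
    w1$inpatient <- ifelse(is.na(w1$inpatient), NA, 0)
    w3$inpatient <- ifelse(is.na(w3$inpatient), NA, 0)
  }
  cw <- impute_costs(w1, w3, records)
  breakdown <- cumulate_windows(records, cw$w1, cw$w3, unit_costs, opt)
  six <- breakdown$six_month

  effects <- scenario_effects(scenario)
  res <- lapply(effects, function(ek) {
    datasets <- analysis_datasets(imputed, six, ek, outcome_cfg)
    grid_key <- if (ek == "qaly_eq5d") "qaly" else ek
    cloud <- bootstrap_cloud(datasets, B = B,
                             seed = derive_seed(seed, paste0("boot-", ek)),
                             effect_kind = ek)
    ci <- percentile_ci(cloud)
    out <- list(
      effect_kind = ek,
      delta_cost = attr(cloud, "delta_cost_hat"),
      delta_effect = attr(cloud, "delta_effect_hat"),
      ci_cost = ci$cost,
      ci_effect = ci$effect,
      icer = icer(attr(cloud, "delta_cost_hat"),
                  attr(cloud, "delta_effect_hat")),
      icer_range = ci$icer_range,
      plane = plane_distribution(cloud),
      ceac = ceac(cloud, wtp_grids[[grid_key]])
    )
    if (keep_cloud) out$cloud <- cloud
    out
  })
  names(res) <- effects
  structure(list(scenario = scenario, effects = res, breakdown = breakdown,
                 B = B, m = m, seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$scenario, sprintf("(B = %d, m = %d, seed = %d)\n",
                                       x$B, x$m, x$seed))
  for (e in x$effects) {
    cat(sprintf("  %-12s dCost = %8.0f EUR  dEffect = %8.4f  ",
                e$effect_kind, e$delta_cost, e$delta_effect))
    print(e$icer)
  }
  invisible(x)
}

#' Table of per-arm mean costs by category
#'
#' Renders the cost breakdown as per-arm means (SD) per category with the
#' incremental difference, in the conventional reporting order (health-care,
#' patient/family, productivity categories, then group totals and the
#' overall total). Amounts are rounded half-up to whole euros at this
#' reporting step only, so rounded components need not sum exactly to the
#' rounded totals.
#'
#' @param breakdown A `cost_breakdown`.
#' @return Data.frame with columns `category`, `mean_ismi`, `sd_ismi`,
#'   `mean_wlc`, `sd_wlc`, `difference`.
#' @export
render_table1 <- function(breakdown) {
  six <- breakdown$six_month
  rows <- c(COST_CATEGORIES, names(COST_GROUPS), "total")
  out <- do.call(rbind, lapply(rows, function(cat) {
    x1 <- six[[cat]][six$arm == "ISMI"]
    x0 <- six[[cat]][six$arm == "WLC"]
    data.frame(category = cat,
               mean_ismi = round_half_up(mean(x1)),
               sd_ismi = round_half_up(stats::sd(x1)),
               mean_wlc = round_half_up(mean(x0)),
               sd_wlc = round_half_up(stats::sd(x0)),
               difference = round_half_up(mean(x1) - mean(x0)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full evaluation pipeline
#'
#' Executes read/validate -> outcome imputation -> costing -> cost
#' imputation -> decision analysis for every requested scenario, and
#' optionally writes a machine-readable report bundle: the per-category cost
#' table (CSV), per-scenario incremental summaries (JSON), CEAC tables (CSV)
#' and plane draws (CSV). Rerunning with the same records and seed
#' reproduces every file byte for byte.
#'
#' @param records Participant records, or a path to a trial CSV.
#' @param scenarios Character vector of scenario names (default all five).
#' @param out_dir Optional output directory for the report files.
#' @inheritParams run_scenario
#' @param strict Validation strictness when `records` is a path.
#' @return List of class `trialcea_report` with `table1`, `scenarios` (named
#'   list of `scenario_result`), and the run settings.
#' @export
run_pipeline <- function(records, scenarios = SCENARIOS,
                         unit_costs = default_unit_costs(),
                         drug_prices = read_drug_prices(),
                         B = 5000, m = 10, seed = 1,
                         wtp_grids = default_wtp_grids(),
                         out_dir = NULL, strict = FALSE) {
  if (is.character(records)) records <- read_trial(records, strict = strict)
  scenarios <- match.arg(scenarios, SCENARIOS, several.ok = TRUE)
  results <- lapply(scenarios, function(sc) {
    run_scenario(records, sc, unit_costs, drug_prices,
                 B = B, m = m, seed = seed, wtp_grids = wtp_grids)
  })
  names(results) <- scenarios
  table1 <- if ("main" %in% scenarios) {
    render_table1(results[["main"]]$breakdown)
  } else {
    render_table1(results[[1]]$breakdown)
  }
  report <- structure(list(table1 = table1, scenarios = results,
                           B = B, m = m, seed = seed),
                      class = "trialcea_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table1, file.path(out_dir, "table1_costs.csv"),
                   row.names = FALSE)
  summaries <- lapply(report$scenarios, function(sc) {
    lapply(sc$effects, function(e) {
      list(delta_cost = e$delta_cost, delta_effect = e$delta_effect,
           ci_cost = e$ci_cost, ci_effect = e$ci_effect,
           icer_label = e$icer$label, icer_value = e$icer$value,
           icer_range = e$icer_range, plane = as.list(e$plane))
    })
  })
  jsonlite::write_json(
    list(seed = report$seed, B = report$B, m = report$m,
         scenarios = summaries),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  for (sc_name in names(report$scenarios)) {
    sc <- report$scenarios[[sc_name]]
    for (e in sc$effects) {
      stem <- paste0(sc_name, "_", e$effect_kind)
      utils::write.csv(as.data.frame(e$ceac),
                       file.path(out_dir, paste0("ceac_", stem, ".csv")),
                       row.names = FALSE)
      if (!is.null(e$cloud)) {
        utils::write.csv(as.data.frame(e$cloud),
                         file.path(out_dir, paste0("plane_", stem, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  invisible(out_dir)
}

#' @export
print.trialcea_report <- function(x, ...) {
  cat("Trial-based cost-effectiveness report",
      sprintf("(B = %d, m = %d, seed = %d)\n", x$B, x$m, x$seed))
  for (sc in x$scenarios) print(sc)
  invisible(x)
}
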