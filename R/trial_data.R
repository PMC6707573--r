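#' Read a wide trial dataset
#'
#' Reads a delimited text file with one row per participant (see
#' [trial_schema()] for the column contract), validates it, and derives the
#' `dropout` flag (follow-up PSS missing). Empty cells are missing values,
#' never zeros: a cost of 0 is a real observation.
#'
#' @param path Path to a CSV (or TSV, with `sep = "\t"`) file with a header.
#' @param strict Logical; when `TRUE` the trial inclusion rule (baseline
#'   PSS-10 at or above the cutoff) is enforced in addition to range checks.
#'   Defaults to `FALSE` for user data, which may legitimately violate
#'   inclusion rules; synthetic data is validated strictly.
#' @param inclusion_cutoff Baseline PSS-10 inclusion threshold (default 22).
#' @param sep Field separator (default `","`).
#' @return A validated data.frame of participant records with an extra
#'   logical `dropout` column.
#' @export
read_trial <- function(path, strict = FALSE, inclusion_cutoff = 22, sep = ",") {
  if (!file.exists(path)) tc_stop("trial file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = "", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  schema <- trial_schema()
  missing_cols <- setdiff(schema$column, names(df))
  if (length(missing_cols) > 0) {
    tc_stop("trial file is missing mandatory column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(df), schema$column)
  if (length(unknown) > 0) {
    tc_warn("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    df <- df[schema$column]
  }
  num_cols <- schema$column[schema$type == "numeric"]
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df <- df[schema$column]
  validate_trial(df, strict = strict, inclusion_cutoff = inclusion_cutoff)
  df$dropout <- is.na(df$pss_t3)
  df
}

#' Write a wide trial dataset
#'
#' Inverse of [read_trial()]: missing values become empty cells (never 0),
#' the derived `dropout` column is not written, and a read/write round trip
#' reproduces the file byte for byte.
#'
#' @param records Data.frame of participant records.
#' @param path Output path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_trial <- function(records, path, sep = ",") {
  schema <- trial_schema()
  out <- records[intersect(schema$column, names(records))]
  missing_cols <- setdiff(schema$column, names(out))
  if (length(missing_cols) > 0) {
    tc_stop("records are missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, na = "", row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) tc_stop("cannot write trial file: ", conditionMessage(ok))
  invisible(path)
}

#' Validate participant records
#'
#' Total validation: every record either passes or raises an error naming the
#' participant id and offending field. Checks arm labels, numeric ranges from
#' [trial_schema()], and (under `strict = TRUE`) the baseline inclusion rule.
#'
#' @inheritParams read_trial
#' @param records Data.frame of participant records.
#' @return `records`, invisibly.
#' @export
validate_trial <- function(records, strict = FALSE, inclusion_cutoff = 22) {
  schema <- trial_schema()
  bad_arm <- !is.na(records$arm) & !(records$arm %in% ARMS)
  if (any(bad_arm)) {
    tc_stop("row ", records$id[which(bad_arm)[1]],
            ": arm must be one of ", paste(ARMS, collapse = "/"),
            ", got '", records$arm[which(bad_arm)[1]], "'")
  }
  if (anyNA(records$arm) || anyNA(records$id)) {
    tc_stop("id and arm may not be missing")
  }
  for (i in which(schema$type == "numeric")) {
    col <- schema$column[i]
    x <- records[[col]]
    bad <- !is.na(x) & (x < schema$min[i] | x > schema$max[i])
    if (any(bad)) {
      tc_stop("row ", records$id[which(bad)[1]], ": ", col, " = ",
              x[which(bad)[1]], " outside [", schema$min[i], ", ",
              schema$max[i], "]")
    }
  }
  pss_int <- c("pss_t1", "pss_t2", "pss_t3")
  for (col in pss_int) {
    x <- records[[col]]
    bad <- !is.na(x) & x != round(x)
    if (any(bad)) {
      tc_stop("row ", records$id[which(bad)[1]], ": ", col,
              " must be an integer score")
    }
  }
  if (strict) {
    bad <- !is.na(records$pss_t1) & records$pss_t1 < inclusion_cutoff
    if (any(bad)) {
      tc_stop("row ", records$id[which(bad)[1]], ": pss_t1 = ",
              records$pss_t1[which(bad)[1]],
              " below the inclusion cutoff ", inclusion_cutoff)
    }
    if (anyNA(records$pss_t1)) tc_stop("baseline PSS missing under strict validation")
  }
  invisible(records)
}

# ---- unit costs -------------------------------------------------------------

# categories whose presence read_unit_costs() requires; prices in 2013 EUR
REQUIRED_UNIT_COSTS <- c(
  "physician_contact", "specialist_contact", "psychological_contact",
  "allied_health_contact", "inpatient_day", "semiresidential_day",
  "rehabilitation_day", "car_km", "opportunity_hour", "informal_care_hour",
  "intervention", "price_index_factor", "ppp_eur_usd", "statutory_share"
)

#' Read a unit-cost table
#'
#' Reads a CSV with columns `category`, `unit_price_eur`, `unit` mapping each
#' resource category to its price in 2013 euros. Rate constants (car
#' kilometre rate 0.30, leisure-time opportunity rate 23.10/h, informal-care
#' substitution rate 18.33/h, intervention tariff 299, consumer price index
#' factor 1.04, purchasing-power parity 1.29 USD/EUR, statutory insurance
#' share 0.888) live in the same table and default to those values; any row
#' in the file overrides the default.
#'
#' @param path Optional path to a CSV; when `NULL` the packaged default
#'   table is returned. Service prices in the packaged table are synthetic
#'   placeholder values; the rate constants are the standard German costing
#'   figures named above.
#' @return An object of class `unit_cost_table` (a data.frame).
#' @export
read_unit_costs <- function(path = NULL) {
  def <- utils::read.csv(system.file("extdata", "unit_costs_synthetic.csv",
                                     package = "trialcea"),
                         stringsAsFactors = FALSE)
  tab <- def
  if (!is.null(path)) {
    user <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("category", "unit_price_eur", "unit")
    if (!all(need %in% names(user))) {
      tc_stop("unit-cost file must have columns: ", paste(need, collapse = ", "))
    }
    if (anyDuplicated(user$category)) {
      tc_stop("duplicate category in unit-cost file: ",
              user$category[duplicated(user$category)][1])
    }
    user$unit_price_eur <- as.numeric(user$unit_price_eur)
    keep <- def[!(def$category %in% user$category), ]
    tab <- rbind(keep, user[names(def)])
  }
  if (anyDuplicated(tab$category)) {
    tc_stop("duplicate category: ", tab$category[duplicated(tab$category)][1])
  }
  if (any(is.na(tab$unit_price_eur)) || any(tab$unit_price_eur < 0)) {
    tc_stop("unit prices must be nonnegative numbers")
  }
  miss <- setdiff(REQUIRED_UNIT_COSTS, tab$category)
  if (length(miss) > 0) {
    tc_stop("unit-cost table lacks required categories: ",
            paste(miss, collapse = ", "))
  }
  rownames(tab) <- NULL
  class(tab) <- c("unit_cost_table", "data.frame")
  tab
}

#' Default unit-cost table
#'
#' Convenience wrapper around [read_unit_costs()] with no file.
#' @return A `unit_cost_table`.
#' @export
default_unit_costs <- function() read_unit_costs(NULL)

#' Look up a unit price
#'
#' @param unit_costs A `unit_cost_table`.
#' @param category Category name(s).
#' @return Numeric price(s) in EUR per natural unit.
#' @export
unit_price <- function(unit_costs, category) {
  idx <- match(category, unit_costs$category)
  if (anyNA(idx)) {
    tc_stop("unknown unit-cost category: ",
            paste(category[is.na(idx)], collapse = ", "))
  }
  unit_costs$unit_price_eur[idx]
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("Unit-cost table (2013 EUR),", nrow(x), "categories\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# ---- drug price table -------------------------------------------------------

#' Read a drug price table
#'
#' Reads a CSV with columns `drug`, `package_size`, `statutory_price_eur`,
#' `private_price_eur`: per-package pharmacy retail prices under statutory
#' and private insurance discounting. Used by [medication_costs()], which
#' averages the up-to-3 largest packages per drug and weights the two
#' insurance prices by the statutory population share.
#'
#' @param path Optional CSV path; `NULL` returns the packaged synthetic
#'   formulary (six drugs, three package sizes each).
#' @return A data.frame of class `drug_price_table`.
#' @export
read_drug_prices <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_prices_synthetic.csv",
                        package = "trialcea")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "package_size", "statutory_price_eur", "private_price_eur")
  if (!all(need %in% names(tab))) {
    tc_stop("drug price file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$statutory_price_eur < 0) || any(tab$private_price_eur < 0)) {
    tc_stop("drug prices must be nonnegative")
  }
  class(tab) <- c("drug_price_table", "data.frame")
  tab
}
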