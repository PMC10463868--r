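# Bottom-up micro-costing: per-patient cost records aggregated into the
# three-group breakdown (direct medical / direct non-medical / indirect),
# with human-capital indirect costs and IRR -> USD conversion.

#' Recognised cost categories
#'
#' The closed set of per-patient cost categories: four direct medical
#' (clinic visits, laboratory, diagnostic imaging/workup, radiotherapy
#' delivery), two direct non-medical (transport to the clinic, lodging),
#' and one indirect (productivity loss valued by the human-capital
#' approach).
#'
#' @return Character vector of category names.
#' @export
cost_categories <- function() {
  c("visits", "laboratory", "diagnosis", "radiotherapy",
    "transport", "lodging", "productivity_loss")
}

cost_groups <- function() {
  list(
    direct_medical     = c("visits", "laboratory", "diagnosis", "radiotherapy"),
    direct_non_medical = c("transport", "lodging"),
    indirect           = "productivity_loss"
  )
}

#' Convert an amount in Iranian Rials to US dollars
#'
#' Applies a single fixed study-period exchange rate. The default rate is
#' 36,692 IRR per USD, the central-bank average for the study period.
#'
#' @param amount Numeric vector of non-negative amounts in IRR.
#' @param irr_per_usd Positive scalar exchange rate (IRR per one USD).
#' @return Numeric vector of amounts in USD.
#' @examples
#' convert_to_usd(36692)          # 1 USD
#' convert_to_usd(91730, 36692)   # 2.50 USD
#' @export
convert_to_usd <- function(amount, irr_per_usd = 36692) {
  if (!is.numeric(amount) || any(is.na(amount)) || any(amount < 0)) {
    abort_invalid("`amount` must be non-negative and non-missing")
  }
  if (!is.numeric(irr_per_usd) || length(irr_per_usd) != 1 ||
      is.na(irr_per_usd) || irr_per_usd <= 0) {
    abort_invalid("`irr_per_usd` must be a single positive number")
  }
  amount / irr_per_usd
}

#' Indirect cost of absenteeism by the human-capital approach
#'
#' Values lost production as days absent times the daily wage, summed over
#' the patient's own absence, a companion's absence, and any paid home
#' nursing. Vectorised over rows of an absenteeism table.
#'
#' @param absentee Data frame with columns `patient_days`, `patient_wage`,
#'   `companion_days`, `companion_wage`, `nursing_days`, `nursing_rate`
#'   (all non-negative; wages are money per day).
#' @return Numeric vector, one indirect cost per row.
#' @examples
#' rec <- tibble::tibble(patient_days = 10, patient_wage = 12,
#'                       companion_days = 5, companion_wage = 8,
#'                       nursing_days = 2, nursing_rate = 20)
#' indirect_cost_human_capital(rec)  # 120 + 40 + 40 = 200
#' @export
indirect_cost_human_capital <- function(absentee) {
  cols <- c("patient_days", "patient_wage", "companion_days",
            "companion_wage", "nursing_days", "nursing_rate")
  missing_cols <- setdiff(cols, names(absentee))
  if (length(missing_cols)) {
    abort_invalid(paste0("absenteeism table lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  }
  vals <- as_tibble(absentee)[cols]
  if (any(vapply(vals, function(x) any(is.na(x)) || any(x < 0), logical(1)))) {
    abort_invalid("absenteeism fields must be non-negative and non-missing")
  }
  vals$patient_days * vals$patient_wage +
    vals$companion_days * vals$companion_wage +
    vals$nursing_days * vals$nursing_rate
}

#' Aggregate per-patient cost records into a cost breakdown
#'
#' Bottom-up aggregation for one strategy arm: amounts in IRR are converted
#' to USD at ingestion, absenteeism records are valued by the human-capital
#' approach and pooled into the `productivity_loss` category, and each
#' category is reported as a mean per patient. Group subtotals (direct
#' medical, direct non-medical, indirect) and the grand total are sums of
#' the category means, so the table matches the per-person presentation of
#' study cost tables. The denominator is the number of distinct patients
#' appearing in either input.
#'
#' @param items Data frame of cost records with columns `patient_id`,
#'   `category` (see [cost_categories()]), `amount` (>= 0), and `currency`
#'   (`"IRR"` or `"USD"`).
#' @param absentee Optional data frame of absenteeism records (see
#'   [indirect_cost_human_capital()]) with a `patient_id` column; wages are
#'   assumed to be in the same `currency` column convention (default USD if
#'   no `currency` column).
#' @param irr_per_usd Exchange rate used for IRR amounts.
#' @return An object of class `cost_breakdown`: a list with `per_category`
#'   (tibble of per-patient category means), the three group totals, the
#'   grand total, and `n_patients`.
#' @export
aggregate_costs <- function(items, absentee = NULL, irr_per_usd = 36692) {
  items <- as_tibble(items)
  req <- c("patient_id", "category", "amount", "currency")
  if (!all(req %in% names(items))) {
    abort_invalid(paste0("cost records need columns: ", paste(req, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(items$category), cost_categories())
  if (length(bad_cat)) {
    abort_invalid(paste0("unknown cost category: ", paste(bad_cat, collapse = ", ")))
  }
  bad_cur <- setdiff(unique(items$currency), c("IRR", "USD"))
  if (length(bad_cur)) {
    abort_invalid(paste0("unknown currency: ", paste(bad_cur, collapse = ", ")))
  }
  if (any(is.na(items$amount)) || any(items$amount < 0)) {
    abort_invalid("cost amounts must be non-negative")
  }

  items <- items %>%
    mutate(amount_usd = ifelse(.data$currency == "IRR",
                               .data$amount / irr_per_usd, .data$amount)) %>%
    select("patient_id", "category", "amount_usd")

  if (!is.null(absentee) && nrow(as_tibble(absentee)) > 0) {
    absentee <- as_tibble(absentee)
    if (!"patient_id" %in% names(absentee)) {
      abort_invalid("absenteeism records need a `patient_id` column")
    }
    ind <- indirect_cost_human_capital(absentee)
    if ("currency" %in% names(absentee)) {
      ind <- ifelse(absentee$currency == "IRR", ind / irr_per_usd, ind)
    }
    items <- bind_rows(items, tibble(patient_id = absentee$patient_id,
                                     category = "productivity_loss",
                                     amount_usd = ind))
  }

  patients <- unique(items$patient_id)
  n_patients <- length(patients)
  if (n_patients < 1) abort_invalid("no patients in the cost records")

  per_category <- items %>%
    group_by(.data$category) %>%
    summarise(total = sum(.data$amount_usd), .groups = "drop") %>%
    mutate(mean_per_patient = .data$total / n_patients)
  per_category <- tibble(category = cost_categories()) %>%
    left_join(per_category, by = "category") %>%
    mutate(mean_per_patient = ifelse(is.na(.data$mean_per_patient), 0,
                                     .data$mean_per_patient)) %>%
    select("category", "mean_per_patient")

  grp <- cost_groups()
  sum_cat <- function(cats) {
    sum(per_category$mean_per_patient[per_category$category %in% cats])
  }
  structure(
    list(
      per_category = per_category,
      direct_medical_total = sum_cat(grp$direct_medical),
      direct_non_medical_total = sum_cat(grp$direct_non_medical),
      indirect_total = sum_cat(grp$indirect),
      grand_total = sum(per_category$mean_per_patient),
      n_patients = n_patients
    ),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Per-patient cost breakdown (USD), n =", x$n_patients, "patients\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @describeIn aggregate_costs Tidy a cost breakdown into a Table-1-shaped
#'   tibble with category rows, the three group subtotal rows, and a
#'   grand-total row.
#' @param x A `cost_breakdown` object.
#' @param ... Unused.
#' @method tidy cost_breakdown
#' @export
tidy.cost_breakdown <- function(x, ...) {
  grp <- cost_groups()
  cat_rows <- x$per_category %>%
    mutate(group = case_when(
      .data$category %in% grp$direct_medical ~ "direct_medical",
      .data$category %in% grp$direct_non_medical ~ "direct_non_medical",
      TRUE ~ "indirect"
    )) %>%
    rename(item = "category", mean_usd = "mean_per_patient") %>%
    select("group", "item", "mean_usd")
  totals <- tibble(
    group = c("direct_medical", "direct_non_medical", "indirect", "total"),
    item = c("total_direct_medical", "total_direct_non_medical",
             "total_indirect", "grand_total"),
    mean_usd = c(x$direct_medical_total, x$direct_non_medical_total,
                 x$indirect_total, x$grand_total)
  )
  bind_rows(cat_rows, totals)
}

#' @describeIn aggregate_costs One-row summary of a cost breakdown.
#' @method glance cost_breakdown
#' @export
glance.cost_breakdown <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    direct_medical_total = x$direct_medical_total,
    direct_non_medical_total = x$direct_non_medical_total,
    indirect_total = x$indirect_total,
    grand_total = x$grand_total
  )
}

#' Truncate a dollar amount to whole dollars
#'
#' Reporting convention: prose figures are the integer part (floor) of the
#' full-precision totals, so 13761.33 reports as 13761. Full precision is
#' retained internally; truncation is applied only at reporting.
#'
#' @param amount Non-negative numeric vector.
#' @return Integer-valued numeric vector, `floor(amount)`.
#' @export
truncate_dollars <- function(amount) {
  if (!is.numeric(amount) || any(is.na(amount)) || any(amount < 0)) {
    abort_invalid("`amount` must be non-negative")
  }
  floor(amount)
}

#' Flag reported totals that disagree with recomputed sums
#'
#' Published cost tables occasionally print subtotals that differ from
#' their own column sums by a cent (transcription rounding). This check
#' recomputes every group subtotal and the grand total from the category
#' means and flags any reported value differing by more than `tol` dollars.
#'
#' @param breakdown A `cost_breakdown` object (the recomputed truth).
#' @param reported Named numeric vector of reported totals; names among
#'   `direct_medical_total`, `direct_non_medical_total`, `indirect_total`,
#'   `grand_total`.
#' @param tol Flagging threshold in dollars (default 0.005, i.e. half a cent).
#' @return Tibble with `quantity`, `recomputed`, `reported`, `discrepancy`,
#'   `flagged`.
#' @export
flag_total_discrepancies <- function(breakdown, reported, tol = 0.005) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  known <- c("direct_medical_total", "direct_non_medical_total",
             "indirect_total", "grand_total")
  bad <- setdiff(names(reported), known)
  if (length(bad)) abort_invalid(paste0("unknown total name: ", paste(bad, collapse = ", ")))
  tibble(
    quantity = names(reported),
    recomputed = unname(vapply(names(reported), function(nm) breakdown[[nm]],
                               numeric(1))),
    reported = as.numeric(reported)
  ) %>%
    mutate(discrepancy = .data$reported - .data$recomputed,
           flagged = abs(.data$discrepancy) > tol)
}

#' Read cost and absenteeism records from delimited text
#'
#' `read_cost_records()` expects columns
#' `patient_id,arm,category,amount,currency`; `read_absenteeism()` expects
#' `patient_id,arm,patient_days,patient_wage,companion_days,companion_wage,nursing_days,nursing_rate`.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_cost_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("patient_id", "arm", "category", "amount", "currency")
  if (!all(req %in% names(df))) {
    abort_invalid(paste0("cost CSV must have columns: ", paste(req, collapse = ", ")))
  }
  df
}

#' @rdname read_cost_records
#' @export
read_absenteeism <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("patient_id", "arm", "patient_days", "patient_wage",
           "companion_days", "companion_wage", "nursing_days", "nursing_rate")
  if (!all(req %in% names(df))) {
    abort_invalid(paste0("absenteeism CSV must have columns: ", paste(req, collapse = ", ")))
  }
  df
}
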