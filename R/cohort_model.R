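cohort_nutrients <- function() {
  c(protein = "protein_g", fiber = "fiber_g", iron = "iron_mg",
    zinc = "zinc_mg", calcium = "calcium_mg", folate = "folate_dfe_ug")
}

cohort_columns <- function() {
  c("person_id", unname(cohort_nutrients()), "beef_serves_per_week")
}

#' Nutrient Reference Values for pregnancy
#'
#' The default thresholds used for compliance modeling: Estimated Average
#' Requirements (EAR) for protein (49 g/day), iron (22 mg), zinc (9.0 mg),
#' calcium (840 mg), and dietary folate equivalents (520 ug), and the
#' Adequate Intake (AI) for dietary fiber (28 g). An intake meets its NRV
#' when the daily amount is at or above the threshold; AI values are applied
#' with the same rule as EARs.
#'
#' @return A tibble with columns `nutrient`, `kind` (`"EAR"`/`"AI"`), and
#'   `threshold` (daily amount in the nutrient's unit).
#' @export
nrv_pregnancy <- function() {
  tibble::tibble(
    nutrient = c("protein", "fiber", "iron", "zinc", "calcium", "folate"),
    kind = c("EAR", "AI", "EAR", "EAR", "EAR", "EAR"),
    threshold = c(49, 28, 22, 9.0, 840, 520)
  )
}

validate_nrv_table <- function(nrvs) {
  missing <- setdiff(c("nutrient", "kind", "threshold"), names(nrvs))
  if (length(missing) > 0) {
    stop_input(paste0("NRV table is missing column(s): ",
                      paste(missing, collapse = ", ")),
               "sustainaswap_schema_error")
  }
  unknown <- setdiff(nrvs$nutrient, names(cohort_nutrients()))
  if (length(unknown) > 0) {
    stop_input(paste0("unknown NRV nutrient(s): ",
                      paste(unknown, collapse = ", "),
                      " (expected ", paste(names(cohort_nutrients()),
                                           collapse = ", "), ")"),
               "sustainaswap_validation_error")
  }
  if (!all(nrvs$kind %in% c("EAR", "AI"))) {
    stop_input("NRV kind must be 'EAR' or 'AI'", "sustainaswap_validation_error")
  }
  if (any(!is.finite(nrvs$threshold) | nrvs$threshold <= 0)) {
    stop_input("NRV thresholds must be > 0", "sustainaswap_validation_error")
  }
  invisible(tibble::as_tibble(nrvs))
}

#' Read an NRV threshold table from CSV
#'
#' @param path CSV with columns `nutrient`, `kind`, `threshold`.
#' @return A validated NRV tibble.
#' @export
load_nrv_table <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("NRV table file not found: ", path),
               "sustainaswap_io_error")
  }
  validate_nrv_table(readr::read_csv(path, show_col_types = FALSE))
}

validate_cohort <- function(cohort) {
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing) > 0) {
    stop_input(paste0("cohort is missing column(s): ",
                      paste(missing, collapse = ", ")),
               "sustainaswap_schema_error")
  }
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    stop_input("cohort contains no records", "sustainaswap_validation_error")
  }
  for (col in setdiff(cohort_columns(), "person_id")) {
    if (any(!is.finite(cohort[[col]]) | cohort[[col]] < 0)) {
      stop_input(paste0("cohort column ", col, " must be non-negative"),
                 "sustainaswap_validation_error")
    }
  }
  invisible(cohort)
}

#' Read cohort intake records from CSV
#'
#' One row per person, with daily nutrient intakes (`protein_g`, `fiber_g`,
#' `iron_mg`, `zinc_mg`, `calcium_mg`, `folate_dfe_ug`), an identifier
#' `person_id`, and the habitual `beef_serves_per_week`.
#'
#' @param path CSV path.
#' @return A validated cohort tibble.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("cohort file not found: ", path), "sustainaswap_io_error")
  }
  validate_cohort(readr::read_csv(path, comment = "#", show_col_types = FALSE))
}

#' Write cohort intake records to CSV
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @param seed Optional integer recorded in a `#`-prefixed header comment so
#'   a generated cohort documents its own provenance.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  cohort <- validate_cohort(cohort)
  lines <- character()
  if (!is.null(seed)) {
    lines <- paste0("# synthetic cohort generated with seed ", seed)
  }
  body <- utils::capture.output(
    readr::write_csv(cohort[cohort_columns()], stdout())
  )
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Shift a cohort's intakes by a swap's nutrient delta
#'
#' Translates a per-serve swap delta into a daily intake shift (delta / 7 for
#' a weekly swap) and applies it to the cohort. In `per_individual` mode only
#' records satisfying the eligibility rule — by default, consuming at least
#' `min_serves` (1) reference serves per week — are shifted; in `uniform`
#' mode every record is shifted, which reproduces summary tables built by
#' shifting whole distributions. Shifted intakes are floored at zero.
#'
#' @param cohort A cohort tibble.
#' @param swap A `swap_result` from [evaluate_swap()] with a weekly scenario.
#' @param mode `"per_individual"` (default) or `"uniform"`.
#' @param min_serves Eligibility cut-off on `beef_serves_per_week`
#'   (default 1).
#' @param comparator `">="` (default) or `">"` applied to `min_serves`.
#' @return The modified cohort, same shape and order, with an added logical
#'   column `swapped`.
#' @export
apply_swap_to_cohort <- function(cohort, swap,
                                 mode = c("per_individual", "uniform"),
                                 min_serves = 1, comparator = c(">=", ">")) {
  mode <- match.arg(mode)
  comparator <- match.arg(comparator)
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(swap, "swap_result"))
  if (swap$scenario$frequency != "weekly") {
    stop_input(
      "cohort modeling divides the per-serve delta by 7 and requires a weekly swap scenario",
      "sustainaswap_config_error"
    )
  }
  eligible <- if (mode == "uniform") {
    rep(TRUE, nrow(cohort))
  } else if (comparator == ">=") {
    cohort$beef_serves_per_week >= min_serves
  } else {
    cohort$beef_serves_per_week > min_serves
  }
  daily_delta <- swap$nutrient_delta / 7
  for (nutrient in names(cohort_nutrients())) {
    col <- cohort_nutrients()[[nutrient]]
    shift <- daily_delta[[col]]
    cohort[[col]] <- pmax(0, cohort[[col]] + ifelse(eligible, shift, 0))
  }
  cohort$swapped <- eligible
  cohort
}

#' Count and percentage of a cohort meeting each NRV
#'
#' A record meets an NRV when its daily intake of that nutrient is greater
#' than or equal to the threshold; percentages are rounded half-up to whole
#' percent.
#'
#' @param cohort A cohort tibble.
#' @param nrvs NRV table (default [nrv_pregnancy()]).
#' @return A tibble with `nutrient`, `kind`, `threshold`, `n_met`, `pct_met`.
#' @export
nrv_compliance <- function(cohort, nrvs = nrv_pregnancy()) {
  cohort <- validate_cohort(cohort)
  nrvs <- validate_nrv_table(nrvs)
  n <- nrow(cohort)
  dplyr::mutate(
    nrvs,
    n_met = vapply(seq_len(nrow(nrvs)), function(i) {
      col <- cohort_nutrients()[[nrvs$nutrient[i]]]
      sum(cohort[[col]] >= nrvs$threshold[i])
    }, numeric(1)),
    pct_met = round_half_up(100 * .data$n_met / n)
  )
}

#' Summary statistics and NRV compliance per nutrient
#'
#' Mean, sample standard deviation (n - 1 denominator), median, and the
#' 25th/75th percentiles (linear interpolation between order statistics,
#' `quantile()` type 7) of each nutrient's daily intake, together with the
#' NRV compliance columns. A single-record cohort reports SD 0 with a
#' warning.
#'
#' @inheritParams nrv_compliance
#' @return A tibble with one row per NRV nutrient: `nutrient`, `kind`,
#'   `threshold`, `mean`, `sd`, `median`, `q25`, `q75`, `n_met`, `pct_met`.
#' @export
summarize_cohort <- function(cohort, nrvs = nrv_pregnancy()) {
  cohort <- validate_cohort(cohort)
  nrvs <- validate_nrv_table(nrvs)
  if (nrow(cohort) == 1) {
    warn("single-record cohort: SD is undefined and reported as 0")
  }
  stats <- lapply(nrvs$nutrient, function(nutrient) {
    x <- cohort[[cohort_nutrients()[[nutrient]]]]
    tibble::tibble(
      nutrient = nutrient,
      mean = mean(x),
      sd = if (length(x) > 1) sd(x) else 0,
      median = median(x),
      q25 = unname(quantile(x, 0.25, type = 7)),
      q75 = unname(quantile(x, 0.75, type = 7))
    )
  })
  dplyr::left_join(
    dplyr::left_join(nrvs, dplyr::bind_rows(stats), by = "nutrient"),
    nrv_compliance(cohort, nrvs)[c("nutrient", "n_met", "pct_met")],
    by = "nutrient"
  )
}
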