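#' Nutrient components tracked per serve
#'
#' The per-serve nutrient profile covers the nutrients prioritised for
#' pregnancy — protein, saturated fat, dietary fiber, iron, zinc, calcium,
#' iodine, and folate (as dietary folate equivalents) — plus energy, which
#' anchors the isoenergetic matching.
#'
#' @return Character vector of nutrient column names used throughout the
#'   package (`protein_g`, `sfa_g`, `fiber_g`, `iron_mg`, `zinc_mg`,
#'   `calcium_mg`, `iodine_ug`, `folate_dfe_ug`, `energy_kj`).
#' @export
nutrient_columns <- function() {
  c("protein_g", "sfa_g", "fiber_g", "iron_mg", "zinc_mg", "calcium_mg",
    "iodine_ug", "folate_dfe_ug", "energy_kj")
}

food_table_columns <- function() {
  c("name", "origin", "serve_weight_cooked_g", "serve_weight_retail_kg",
    "energy_kj", "protein_g", "sfa_g", "fiber_g", "iron_mg", "zinc_mg",
    "calcium_mg", "iodine_ug", "folate_dfe_ug", intensity_columns())
}

intensity_columns <- function() {
  c("ghg_kgco2e_per_kg", "land_m2_per_kg", "acid_gso2e_per_kg",
    "eutroph_gpo4e_per_kg", "water_l_per_kg")
}

#' Validate a food-composition table
#'
#' Checks the schema and value invariants a food table must satisfy: all
#' required columns present, unique food names, origin one of
#' `"animal"`/`"plant"`, strictly positive serve weights and energy, and no
#' negative nutrient or intensity values.
#'
#' @param table A data frame of foods (one row per food).
#' @return The table, invisibly coerced to a tibble, if valid; otherwise an
#'   error of class `sustainaswap_schema_error` or
#'   `sustainaswap_validation_error`.
#' @export
validate_food_table <- function(table) {
  missing <- setdiff(food_table_columns(), names(table))
  if (length(missing) > 0) {
    stop_input(
      paste0("food table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      "sustainaswap_schema_error"
    )
  }
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) {
    stop_input("food table contains no rows", "sustainaswap_schema_error")
  }
  if (anyDuplicated(table$name) > 0) {
    stop_input(
      paste0("duplicate food name(s): ",
             paste(unique(table$name[duplicated(table$name)]), collapse = ", ")),
      "sustainaswap_validation_error"
    )
  }
  if (!all(table$origin %in% c("animal", "plant"))) {
    bad <- table$name[!table$origin %in% c("animal", "plant")]
    stop_input(
      paste0("origin must be 'animal' or 'plant' for: ",
             paste(bad, collapse = ", ")),
      "sustainaswap_validation_error"
    )
  }
  numeric_cols <- setdiff(food_table_columns(), c("name", "origin"))
  for (col in numeric_cols) {
    bad <- !is.finite(table[[col]]) | table[[col]] < 0
    if (any(bad)) {
      stop_input(
        paste0("negative or non-finite ", col, " for: ",
               paste(table$name[bad], collapse = ", ")),
        "sustainaswap_validation_error"
      )
    }
  }
  strictly_positive <- c("serve_weight_cooked_g", "serve_weight_retail_kg",
                         "energy_kj")
  for (col in strictly_positive) {
    bad <- table[[col]] <= 0
    if (any(bad)) {
      stop_input(
        paste0(col, " must be > 0 for: ", paste(table$name[bad], collapse = ", ")),
        "sustainaswap_validation_error"
      )
    }
  }
  invisible(table)
}

#' Read a food-composition table from CSV
#'
#' The CSV must carry one row per food with columns `name`, `origin`
#' (`animal`/`plant`), `serve_weight_cooked_g`, `serve_weight_retail_kg`, the
#' nine nutrient columns of [nutrient_columns()], and five per-kilogram
#' environmental intensity columns (`ghg_kgco2e_per_kg`, `land_m2_per_kg`,
#' `acid_gso2e_per_kg`, `eutroph_gpo4e_per_kg`, `water_l_per_kg`).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A validated tibble of foods.
#' @seealso [example_food_table()] for the bundled beef-alternatives table,
#'   [write_food_table()] for the inverse operation.
#' @export
load_food_table <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("food table file not found: ", path),
               "sustainaswap_io_error")
  }
  table <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE),
    error = function(e) {
      stop_input(paste0("could not parse food table CSV: ", conditionMessage(e)),
                 "sustainaswap_schema_error")
    }
  )
  table <- validate_food_table(table)
  message(nrow(table), " foods loaded from ", basename(path))
  invisible(table)
}

#' Write a food-composition table to CSV
#'
#' @param table A validated food table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(table, path) {
  table <- validate_food_table(table)
  readr::write_csv(table[food_table_columns()], path)
  invisible(path)
}

#' Bundled food table: beef and its sustainable alternatives
#'
#' Per-serve nutrient profiles for beef and thirteen lower-emission
#' alternatives (other meats, egg, fish, pulses, tofu, nuts). Every serve is
#' isoenergetic with the 471 kJ standard cooked beef serve, so the bundled
#' serves are directly comparable. Environmental intensities are global mean
#' life-cycle values per kilogram of retail weight; retail serve weights were
#' derived from the greenhouse-gas budget of one weekly serve over a 270-day
#' pregnancy divided by the per-kilogram intensity (see the package vignette
#' and `inst/extdata/README.md` for the derivation).
#'
#' @return A validated tibble with 14 foods.
#' @export
example_food_table <- function() {
  path <- system.file("extdata", "beef_alternatives.csv",
                      package = "sustainaswap", mustWork = TRUE)
  suppressMessages(load_food_table(path))
}

#' Look up a single food by name
#'
#' @param table A food table.
#' @param name Food name, matched exactly.
#' @return The one-row tibble for that food.
#' @export
food_item <- function(table, name) {
  table <- validate_food_table(table)
  hit <- table[table$name == name, ]
  if (nrow(hit) != 1) {
    stop_input(paste0("food not found in table: ", name),
               "sustainaswap_lookup_error")
  }
  hit
}

#' Energy density of a food's cooked serve
#'
#' @param food A one-row food tibble (see [food_item()]).
#' @return Energy density in kJ per gram cooked weight.
#' @examples
#' tab <- example_food_table()
#' energy_density(food_item(tab, "Beef")) # 471 kJ / 65 g = 7.246
#' @export
energy_density <- function(food) {
  stopifnot(nrow(food) == 1)
  if (food$serve_weight_cooked_g <= 0) {
    stop_input("serve_weight_cooked_g must be > 0", "sustainaswap_validation_error")
  }
  food$energy_kj / food$serve_weight_cooked_g
}

#' Rank foods by their contribution to daily energy or protein intake
#'
#' Given per-food daily contributions (e.g. derived from a food-frequency
#' questionnaire), returns the top contributors by the chosen field. The sort
#' is stable: tied foods keep their input order.
#'
#' @param intakes Data frame with columns `food`, `energy_kj_per_day`,
#'   `protein_g_per_day` (non-negative).
#' @param by Ranking field: `"energy"` or `"protein"`.
#' @param top_n Number of foods to keep (>= 1).
#' @return A tibble of the `top_n` largest contributors in descending order.
#' @export
rank_contributors <- function(intakes, by = c("energy", "protein"), top_n = 10L) {
  by <- tryCatch(match.arg(by), error = function(e) {
    stop_input("`by` must be 'energy' or 'protein'", "sustainaswap_usage_error")
  })
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1) {
    stop_input("`top_n` must be a single count >= 1", "sustainaswap_usage_error")
  }
  required <- c("food", "energy_kj_per_day", "protein_g_per_day")
  missing <- setdiff(required, names(intakes))
  if (length(missing) > 0) {
    stop_input(paste0("intake table is missing column(s): ",
                      paste(missing, collapse = ", ")),
               "sustainaswap_schema_error")
  }
  col <- if (by == "energy") "energy_kj_per_day" else "protein_g_per_day"
  if (any(intakes[[col]] < 0)) {
    stop_input("intake contributions must be >= 0", "sustainaswap_validation_error")
  }
  intakes <- tibble::as_tibble(intakes)
  ord <- order(-intakes[[col]])  # stable: order() preserves ties in input order
  head(intakes[ord, ], n = as.integer(top_n))
}
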