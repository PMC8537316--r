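#' Configure a full swap-modeling run
#'
#' Bundles everything [run_pipeline()] needs: the food table, the swap
#' scenarios to tabulate, the cohort (a CSV path or a synthetic-cohort
#' configuration), the NRV thresholds, the model constants, and the cohort
#' scenario whose before/after summary is reported.
#'
#' @param food_table A food table tibble (default [example_food_table()]).
#' @param scenarios List of [swap_scenario()]s for the swap report; default
#'   is every food in the table as an isoenergetic weekly alternative to the
#'   first food (the reference).
#' @param cohort Either a cohort CSV path, a cohort tibble, or a
#'   [synthetic_cohort_config()] (the default, seeded from `seed`).
#' @param nrvs NRV table (default [nrv_pregnancy()]).
#' @param cohort_scenario The single [swap_scenario()] applied to the cohort
#'   (default: the first entry of `scenarios`).
#' @param mode Cohort shift mode, `"per_individual"` or `"uniform"`.
#' @param params [iron_absorption_params()].
#' @param equiv [vehicle_equivalence()].
#' @param seed Integer seed used for cohort generation (default 20210924).
#' @return A `run_config` list.
#' @export
run_config <- function(food_table = example_food_table(),
                       scenarios = NULL,
                       cohort = NULL,
                       nrvs = nrv_pregnancy(),
                       cohort_scenario = NULL,
                       mode = c("per_individual", "uniform"),
                       params = iron_absorption_params(),
                       equiv = vehicle_equivalence(),
                       seed = 20210924) {
  mode <- match.arg(mode)
  food_table <- validate_food_table(food_table)
  if (is.null(scenarios)) {
    reference <- food_table$name[1]
    scenarios <- lapply(setdiff(food_table$name, reference), function(alt) {
      swap_scenario(reference, alt, basis = "energy", frequency = "weekly")
    })
  }
  if (length(scenarios) == 0) {
    stop_input("at least one swap scenario is required",
               "sustainaswap_config_error")
  }
  if (is.null(cohort)) {
    cohort <- synthetic_cohort_config(seed = seed)
  }
  if (is.null(cohort_scenario)) cohort_scenario <- scenarios[[1]]
  structure(
    list(food_table = food_table, scenarios = scenarios, cohort = cohort,
         nrvs = validate_nrv_table(nrvs), cohort_scenario = cohort_scenario,
         mode = mode, params = params, equiv = equiv, seed = seed),
    class = "run_config"
  )
}

pipeline_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)),
            class = "sustainaswap_pipeline_error", parent = e)
    }),
    warning = function(w) {
      warn(paste0("[", stage, "] ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
}

#' Run the full substitution-modeling pipeline
#'
#' Produces four CSV reports in `out_dir`:
#' \describe{
#'   \item{`matched_serves.csv`}{Nutrient profile of each scenario's matched
#'     alternative serve, including estimated absorbed iron.}
#'   \item{`footprints.csv`}{Per-serve and per-pregnancy environmental
#'     footprint of each food, with vehicle-km equivalents.}
#'   \item{`swap_deltas.csv`}{Net nutrient and footprint deltas per scenario.}
#'   \item{`cohort_summary.csv`}{Before/after cohort summary statistics and
#'     NRV compliance for the cohort scenario.}
#' }
#' plus `run_info.txt` recording the package version, seed, and constants.
#' Runs are deterministic: the same config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of the four report tibbles and the output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("swaprun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  table <- config$food_table

  cohort <- pipeline_stage("cohort", {
    if (inherits(config$cohort, "synthetic_cohort_config")) {
      generate_cohort(config$cohort)
    } else if (is.character(config$cohort)) {
      load_cohort(config$cohort)
    } else {
      validate_cohort(config$cohort)
    }
  })

  matched <- pipeline_stage("matching", {
    dplyr::bind_rows(lapply(config$scenarios, function(sc) {
      ref <- food_item(table, sc$reference)
      alt <- food_item(table, sc$alternative)
      serve <- matched_serve(alt, ref, sc$basis)
      serve$reference <- sc$reference
      serve$absorbed_iron_mg <- round_half_up(
        absorbed_iron(serve$iron_mg, serve$origin, config$params), 2
      )
      serve$weight_cooked_g <- round_half_up(serve$weight_cooked_g)
      dplyr::mutate(serve, dplyr::across(dplyr::all_of(nutrient_columns()),
                                         \(x) round_half_up(x, 1)))
    }))
  })

  footprints <- pipeline_stage("footprint", {
    dplyr::bind_rows(lapply(config$scenarios, function(sc) {
      serve <- matched_serve(food_item(table, sc$alternative),
                             food_item(table, sc$reference), sc$basis)
      per_serve <- serve_footprint(serve)
      preg <- pregnancy_footprint(per_serve, sc$duration_days, sc$frequency)
      tibble::tibble(
        food = sc$alternative,
        basis = sc$basis,
        serve_ghg_kgco2e = round_half_up(per_serve[["ghg_kgco2e"]], 1),
        serve_land_m2 = round_half_up(per_serve[["land_m2"]], 1),
        serve_acid_gso2e = round_half_up(per_serve[["acid_gso2e"]], 1),
        serve_eutroph_gpo4e = round_half_up(per_serve[["eutroph_gpo4e"]], 1),
        serve_water_l = round_half_up(per_serve[["water_l"]], 1),
        pregnancy_ghg_kgco2e = round_half_up(preg[["ghg_kgco2e"]], 1),
        pregnancy_km_equivalent = car_km_equivalent(preg[["ghg_kgco2e"]],
                                                    config$equiv),
        pregnancy_land_m2 = round_half_up(preg[["land_m2"]], 1),
        pregnancy_acid_gso2e = round_half_up(preg[["acid_gso2e"]], 1),
        pregnancy_eutroph_gpo4e = round_half_up(preg[["eutroph_gpo4e"]], 1),
        pregnancy_water_l = round_half_up(preg[["water_l"]], 1)
      )
    }))
  })

  deltas <- pipeline_stage("swap_engine", {
    swap_report(table, config$scenarios, config$params, config$equiv)
  })

  cohort_summary <- pipeline_stage("cohort_model", {
    swap <- evaluate_swap(table, config$cohort_scenario, config$params,
                          config$equiv)
    before <- summarize_cohort(cohort, config$nrvs)
    after <- summarize_cohort(
      apply_swap_to_cohort(cohort, swap, mode = config$mode), config$nrvs
    )
    dplyr::bind_rows(
      dplyr::mutate(before, intake = "original", .before = 1),
      dplyr::mutate(after, intake = "modeled", .before = 1)
    )
  })

  paths <- list(
    matched_serves = file.path(out_dir, "matched_serves.csv"),
    footprints = file.path(out_dir, "footprints.csv"),
    swap_deltas = file.path(out_dir, "swap_deltas.csv"),
    cohort_summary = file.path(out_dir, "cohort_summary.csv")
  )
  readr::write_csv(matched, paths$matched_serves)
  readr::write_csv(footprints, paths$footprints)
  readr::write_csv(deltas, paths$swap_deltas)
  readr::write_csv(cohort_summary, paths$cohort_summary)

  writeLines(c(
    paste0("sustainaswap ", as.character(utils::packageVersion("sustainaswap"))),
    paste0("seed: ", config$seed),
    paste0("duration_days: ", config$cohort_scenario$duration_days),
    paste0("iron params: heme_fraction_animal=",
           config$params$heme_fraction_animal,
           " nonheme_absorption=", config$params$nonheme_absorption,
           " heme_absorption=", config$params$heme_absorption),
    paste0("vehicle: kg_co2e_per_mile=", config$equiv$kg_co2e_per_mile,
           " km_per_mile=", config$equiv$km_per_mile),
    paste0("cohort mode: ", config$mode),
    paste0("cohort n: ", nrow(cohort))
  ), file.path(out_dir, "run_info.txt"))

  invisible(list(matched_serves = matched, footprints = footprints,
                 swap_deltas = deltas, cohort_summary = cohort_summary,
                 cohort = cohort, paths = paths, out_dir = out_dir))
}
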