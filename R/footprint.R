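footprint_metrics <- function() {
  c(ghg_kgco2e = "ghg_kgco2e_per_kg",
    land_m2 = "land_m2_per_kg",
    acid_gso2e = "acid_gso2e_per_kg",
    eutroph_gpo4e = "eutroph_gpo4e_per_kg",
    water_l = "water_l_per_kg")
}

#' Environmental footprint of one matched serve
#'
#' Each metric is the food's per-kilogram intensity times the retail weight
#' of the serve: greenhouse gas (kg CO2 eq), land use (m2-years), acidifying
#' emissions (g SO2 eq), eutrophying emissions (g PO4(3-) eq), and
#' stress-weighted water use (L).
#'
#' @param serve A matched serve from [matched_serve()].
#' @return A named numeric vector with components `ghg_kgco2e`, `land_m2`,
#'   `acid_gso2e`, `eutroph_gpo4e`, `water_l`.
#' @export
serve_footprint <- function(serve) {
  stopifnot(nrow(serve) == 1)
  metrics <- footprint_metrics()
  out <- vapply(metrics, function(col) serve[[col]] * serve$weight_retail_kg,
                numeric(1))
  names(out) <- names(metrics)
  out
}

#' Footprint of repeating one serve over a pregnancy
#'
#' One serve per week over a 270-day pregnancy amounts to 270/7 (about 38.6)
#' serves; a daily habit amounts to 270 serves. The weekly count is kept
#' fractional rather than truncated to whole weeks.
#'
#' @param per_serve A footprint vector from [serve_footprint()] (or any
#'   signed footprint delta).
#' @param duration_days Pregnancy duration in days (default 270, > 0).
#' @param frequency `"weekly"` or `"daily"`.
#' @return Footprint vector scaled to the full duration.
#' @export
pregnancy_footprint <- function(per_serve, duration_days = 270,
                                frequency = c("weekly", "daily")) {
  frequency <- match.arg(frequency)
  if (!is.numeric(duration_days) || length(duration_days) != 1 ||
      duration_days < 0) {
    stop_input("duration_days must be a single non-negative number",
               "sustainaswap_validation_error")
  }
  serves <- if (frequency == "weekly") duration_days / 7 else duration_days
  per_serve * serves
}

#' Passenger-vehicle emission equivalence
#'
#' Converts a greenhouse-gas mass to the distance an average passenger
#' vehicle would drive to emit it. The default factor of 0.400 kg CO2 eq per
#' mile follows the US EPA greenhouse-gas equivalencies calculator.
#'
#' @param kg_co2e_per_mile Vehicle emission factor (default 0.400, > 0).
#' @param km_per_mile Miles-to-kilometres conversion (default 1.60934).
#' @return A list with the two constants.
#' @export
vehicle_equivalence <- function(kg_co2e_per_mile = 0.400,
                                km_per_mile = 1.60934) {
  if (kg_co2e_per_mile <= 0 || km_per_mile <= 0) {
    stop_input("vehicle equivalence factors must be > 0",
               "sustainaswap_validation_error")
  }
  structure(list(kg_co2e_per_mile = kg_co2e_per_mile,
                 km_per_mile = km_per_mile),
            class = "vehicle_equivalence")
}

#' Kilometres of typical driving equivalent to a GHG mass
#'
#' @param ghg_kgco2e Greenhouse-gas mass in kg CO2 eq (non-negative;
#'   vectorised).
#' @param equiv Constants from [vehicle_equivalence()].
#' @param round Round to whole kilometres, the reporting convention
#'   (default TRUE).
#' @return Equivalent driving distance in km.
#' @examples
#' car_km_equivalent(372.2) # ~1498 km
#' @export
car_km_equivalent <- function(ghg_kgco2e, equiv = vehicle_equivalence(),
                              round = TRUE) {
  if (any(!is.finite(ghg_kgco2e)) || any(ghg_kgco2e < 0)) {
    stop_input("ghg_kgco2e must be non-negative; pass the magnitude of a reduction",
               "sustainaswap_validation_error")
  }
  km <- ghg_kgco2e / equiv$kg_co2e_per_mile * equiv$km_per_mile
  if (round) round_half_up(km) else km
}
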