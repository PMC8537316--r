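#' Iron absorption assumptions
#'
#' Within a mixed diet, iron in plant foods is entirely non-heme, while iron
#' in animal-derived foods is taken to be 40% heme and 60% non-heme; 16.8% of
#' non-heme and 25% of heme iron are absorbed. These defaults are
#' deliberately conservative for pregnancy, during which non-heme absorption
#' is up-regulated, and can be overridden for sensitivity analyses.
#'
#' @param heme_fraction_animal Proportion of iron in animal foods that is
#'   heme-bound (default 0.40).
#' @param nonheme_absorption Absorbed fraction of non-heme iron (default 0.168).
#' @param heme_absorption Absorbed fraction of heme iron (default 0.25).
#' @return A list of the three proportions, validated to lie in \[0, 1\].
#' @export
iron_absorption_params <- function(heme_fraction_animal = 0.40,
                                   nonheme_absorption = 0.168,
                                   heme_absorption = 0.25) {
  p <- list(
    heme_fraction_animal = heme_fraction_animal,
    nonheme_absorption = nonheme_absorption,
    heme_absorption = heme_absorption
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop_input(paste0(nm, " must be a single proportion in [0, 1]"),
                 "sustainaswap_validation_error")
    }
  }
  structure(p, class = "iron_absorption_params")
}

#' Estimated absorbed iron
#'
#' For plant foods, absorbed iron is total iron times the non-heme absorption
#' fraction. For animal foods it is a mixture: the non-heme share of the iron
#' times non-heme absorption plus the heme share times heme absorption
#' (0.6 x 0.168 + 0.4 x 0.25 = 0.2008 with the defaults).
#'
#' @param iron_mg Total iron, mg (vectorised, non-negative).
#' @param origin `"animal"` or `"plant"`, recycled against `iron_mg`.
#' @param params Absorption assumptions from [iron_absorption_params()].
#' @return Estimated absorbed iron in mg, unrounded.
#' @examples
#' absorbed_iron(3.8, "plant")  # silken tofu serve: 0.64 mg at 2 dp
#' absorbed_iron(0.8, "animal") # pork serve: 0.16 mg at 2 dp
#' @export
absorbed_iron <- function(iron_mg, origin, params = iron_absorption_params()) {
  if (!inherits(params, "iron_absorption_params")) {
    params <- do.call(iron_absorption_params, params)
  }
  if (any(!is.finite(iron_mg)) || any(iron_mg < 0)) {
    stop_input("iron_mg must be non-negative", "sustainaswap_validation_error")
  }
  if (!all(origin %in% c("animal", "plant"))) {
    stop_input("origin must be 'animal' or 'plant'",
               "sustainaswap_validation_error")
  }
  multiplier <- ifelse(
    origin == "plant",
    params$nonheme_absorption,
    (1 - params$heme_fraction_animal) * params$nonheme_absorption +
      params$heme_fraction_animal * params$heme_absorption
  )
  iron_mg * multiplier
}
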