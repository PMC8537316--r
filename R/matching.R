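#' Scale an alternative food's serve to match a reference serve
#'
#' The central portioning step of the substitution model. An alternative
#' food's standard serve is rescaled so that its energy (isoenergetic match)
#' or protein content (protein match) equals that of one reference serve;
#' `basis = "fixed"` keeps the alternative's own standard serve, which is the
#' appropriate choice for like-for-like daily swaps such as milk for soy
#' milk. All nutrients, the cooked weight, and the retail weight scale
#' linearly with the matching factor; nothing is rounded internally.
#'
#' @param alt One-row tibble for the alternative food (see [food_item()]).
#' @param ref One-row tibble for the reference food.
#' @param basis `"energy"`, `"protein"`, or `"fixed"`.
#' @return A one-row tibble with the food's `name` and `origin`, the `basis`,
#'   the dimensionless `scale` relative to the alternative's standard serve,
#'   scaled `weight_cooked_g` and `weight_retail_kg`, the scaled nutrient
#'   columns, and the (unscaled, per-kg) environmental intensity columns.
#' @examples
#' tab <- example_food_table()
#' matched_serve(food_item(tab, "Tofu, firm"), food_item(tab, "Beef"), "energy")
#' @export
matched_serve <- function(alt, ref, basis = c("energy", "protein", "fixed")) {
  basis <- match.arg(basis)
  stopifnot(nrow(alt) == 1, nrow(ref) == 1)
  scale <- switch(basis,
    energy = {
      if (alt$energy_kj <= 0) {
        stop_input(paste0("cannot energy-match '", alt$name,
                          "': per-serve energy is not positive"),
                   "sustainaswap_validation_error")
      }
      ref$energy_kj / alt$energy_kj
    },
    protein = {
      if (alt$protein_g <= 0) {
        stop_input(paste0("cannot protein-match '", alt$name,
                          "': per-serve protein is not positive"),
                   "sustainaswap_validation_error")
      }
      ref$protein_g / alt$protein_g
    },
    fixed = 1
  )
  out <- tibble::tibble(
    name = alt$name,
    origin = alt$origin,
    basis = basis,
    scale = scale,
    weight_cooked_g = alt$serve_weight_cooked_g * scale,
    weight_retail_kg = alt$serve_weight_retail_kg * scale
  )
  for (col in nutrient_columns()) {
    out[[col]] <- alt[[col]] * scale
  }
  for (col in intensity_columns()) {
    out[[col]] <- alt[[col]]
  }
  out
}

#' @rdname matched_serve
#' @export
isoenergetic_serve <- function(alt, ref) matched_serve(alt, ref, "energy")

#' @rdname matched_serve
#' @export
protein_matched_serve <- function(alt, ref) matched_serve(alt, ref, "protein")
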