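# Small in-code fixtures for unit and property tests.

# Two-food toy table with round numbers, for properties that should not
# depend on the bundled fixture.
toy_food_table <- function() {
  tibble::tibble(
    name = c("RefMeat", "AltBean"),
    origin = c("animal", "plant"),
    serve_weight_cooked_g = c(100, 150),
    serve_weight_retail_kg = c(0.12, 0.15),
    energy_kj = c(500, 250),
    protein_g = c(20, 8),
    sfa_g = c(2, 0.5),
    fiber_g = c(0, 6),
    iron_mg = c(2, 3),
    zinc_mg = c(4, 1),
    calcium_mg = c(10, 60),
    iodine_ug = c(1, 0.5),
    folate_dfe_ug = c(0, 80),
    ghg_kgco2e_per_kg = c(50, 2),
    land_m2_per_kg = c(150, 6),
    acid_gso2e_per_kg = c(200, 10),
    eutroph_gpo4e_per_kg = c(180, 8),
    water_l_per_kg = c(20000, 3000)
  )
}

# Deterministic toy cohort with hand-checkable values.
toy_cohort <- function(iron = c(10, 22, 23, 5)) {
  n <- length(iron)
  tibble::tibble(
    person_id = paste0("T", seq_len(n)),
    protein_g = seq(60, by = 10, length.out = n),
    fiber_g = seq(20, by = 2, length.out = n),
    iron_mg = iron,
    zinc_mg = seq(8, by = 1, length.out = n),
    calcium_mg = seq(700, by = 100, length.out = n),
    folate_dfe_ug = seq(200, by = 50, length.out = n),
    beef_serves_per_week = rep(c(0, 2), length.out = n)
  )
}

# Daily energy/protein contributions in the style of an FFQ ranking table.
toy_contributions <- function() {
  tibble::tibble(
    food = c("Rice", "Pasta", "Full-cream milk", "Chocolate", "Yogurt",
             "Chicken", "Cakes", "Beef", "Mixed dishes", "Tropical fruits"),
    energy_kj_per_day = c(539, 518, 281, 271, 236, 199, 148, 142, 131, 123),
    protein_g_per_day = c(2.3, 4.5, 3.4, 0, 3.9, 4.6, 0, 6.4, 1.9, 0)
  )
}
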