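test_that("bundled food table loads with the published serve values", {
  tab <- example_food_table()
  expect_equal(nrow(tab), 14)
  expect_setequal(
    names(tab),
    c("name", "origin", "serve_weight_cooked_g", "serve_weight_retail_kg",
      nutrient_columns(),
      c("ghg_kgco2e_per_kg", "land_m2_per_kg", "acid_gso2e_per_kg",
        "eutroph_gpo4e_per_kg", "water_l_per_kg"))
  )
  beef <- food_item(tab, "Beef")
  expect_equal(beef$serve_weight_cooked_g, 65)
  expect_equal(beef$energy_kj, 471)
  expect_equal(beef$protein_g, 20.2)
  expect_equal(beef$iron_mg, 1.7)
  # every serve in the table is isoenergetic with the beef serve
  expect_true(all(tab$energy_kj == 471))
  # derived retail serve weight for beef is 100 g
  expect_equal(round_half_up(beef$serve_weight_retail_kg, 3), 0.100)
})

test_that("food table round-trips through CSV at full precision", {
  tab <- example_food_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_table(tab, path)
  back <- suppressMessages(load_food_table(path))
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})

test_that("food table validation rejects malformed input", {
  tab <- toy_food_table()
  expect_error(validate_food_table(tab[, -3]),
               class = "sustainaswap_schema_error")
  expect_error(validate_food_table(dplyr::mutate(tab, iron_mg = c(-1, 2))),
               class = "sustainaswap_validation_error")
  expect_error(validate_food_table(dplyr::mutate(tab, name = c("X", "X"))),
               class = "sustainaswap_validation_error")
  expect_error(validate_food_table(dplyr::mutate(tab, origin = c("animal", "mineral"))),
               class = "sustainaswap_validation_error")
  expect_error(validate_food_table(dplyr::mutate(tab, energy_kj = c(0, 250))),
               class = "sustainaswap_validation_error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(suppressWarnings(load_food_table(empty)),
               class = "sustainaswap_schema_error")
  expect_error(load_food_table("no/such/file.csv"),
               class = "sustainaswap_io_error")
})

test_that("energy density divides per-serve energy by cooked weight", {
  tab <- example_food_table()
  expect_equal(energy_density(food_item(tab, "Beef")), 471 / 65,
               tolerance = 1e-12)
  expect_equal(round(energy_density(food_item(tab, "Beef")), 3), 7.246)
  expect_equal(round(energy_density(food_item(tab, "Tofu, firm")), 3), 5.011)
  # doubling both energy and weight leaves the density unchanged
  doubled <- dplyr::mutate(toy_food_table(),
                           energy_kj = energy_kj * 2,
                           serve_weight_cooked_g = serve_weight_cooked_g * 2)
  expect_equal(energy_density(doubled[1, ]),
               energy_density(toy_food_table()[1, ]))
})

test_that("rank_contributors sorts stably and truncates", {
  intakes <- toy_contributions()
  top3 <- rank_contributors(intakes, by = "energy", top_n = 3)
  expect_equal(top3$food, c("Rice", "Pasta", "Full-cream milk"))
  expect_equal(top3$energy_kj_per_day, c(539, 518, 281))

  by_protein <- rank_contributors(intakes, by = "protein", top_n = 4)
  expect_equal(by_protein$food, c("Beef", "Chicken", "Pasta", "Yogurt"))

  # single item and truncation contract
  one <- rank_contributors(intakes[3, ], by = "energy", top_n = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$food, "Full-cream milk")
  expect_equal(nrow(rank_contributors(intakes, by = "energy", top_n = 100)),
               nrow(intakes))

  # ties keep input order (stable sort)
  tied <- tibble::tibble(food = c("A", "B", "C"),
                         energy_kj_per_day = c(100, 200, 100),
                         protein_g_per_day = c(1, 1, 1))
  expect_equal(rank_contributors(tied, by = "energy", top_n = 3)$food,
               c("B", "A", "C"))

  expect_error(rank_contributors(intakes, by = "fat", top_n = 3),
               class = "sustainaswap_usage_error")
  expect_error(rank_contributors(intakes, by = "energy", top_n = 0),
               class = "sustainaswap_usage_error")
})
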