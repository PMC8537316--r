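beef_tofu_swap <- function(basis = "energy") {
  evaluate_swap(example_food_table(),
                swap_scenario("Beef", "Tofu, firm", basis = basis))
}

test_that("NRV compliance matches exhaustive hand counts on a toy cohort", {
  cohort <- toy_cohort(iron = c(10, 22, 23, 5))
  nrvs <- nrv_pregnancy()
  comp <- nrv_compliance(cohort, nrvs)
  expect_equal(comp$n_met[comp$nutrient == "iron"], 2)   # 22, 23 >= 22
  expect_equal(comp$pct_met[comp$nutrient == "iron"], 50)

  # all below threshold
  low <- toy_cohort(iron = c(1, 2, 3, 4))
  expect_equal(nrv_compliance(low, nrvs)$n_met[comp$nutrient == "iron"], 0)

  expect_error(
    nrv_compliance(cohort, dplyr::mutate(nrvs, threshold = 0)),
    class = "sustainaswap_validation_error"
  )
  expect_error(
    nrv_compliance(cohort,
                   tibble::tibble(nutrient = "iodine", kind = "EAR",
                                  threshold = 160)),
    class = "sustainaswap_validation_error"
  )
})

test_that("a uniform weekly shift moves location by delta/7 and leaves spread alone", {
  swap <- beef_tofu_swap()
  cohort <- generate_cohort(synthetic_cohort_config(n = 400, seed = 7))
  before <- summarize_cohort(cohort)
  after <- summarize_cohort(apply_swap_to_cohort(cohort, swap, mode = "uniform"))

  daily <- swap$nutrient_delta / 7
  shifts <- c(protein = daily[["protein_g"]], fiber = daily[["fiber_g"]],
              iron = daily[["iron_mg"]], zinc = daily[["zinc_mg"]],
              calcium = daily[["calcium_mg"]], folate = daily[["folate_dfe_ug"]])
  for (nm in names(shifts)) {
    b <- before[before$nutrient == nm, ]
    a <- after[after$nutrient == nm, ]
    expect_equal(a$mean - b$mean, unname(shifts[nm]), tolerance = 1e-9)
    expect_equal(a$median - b$median, unname(shifts[nm]), tolerance = 1e-9)
    expect_equal(a$q25 - b$q25, unname(shifts[nm]), tolerance = 1e-9)
    expect_equal(a$sd, b$sd, tolerance = 1e-12)
    expect_equal(a$q75 - a$q25, b$q75 - b$q25, tolerance = 1e-9)
  }
})

test_that("uniform shift applied to the published original means reproduces the modeled means", {
  swap <- beef_tofu_swap()
  # two records per nutrient at mean +/- SD: cohort means equal the published
  # original means exactly, so the uniform shift lands on the modeled column
  targets <- default_intake_targets()
  cohort <- tibble::tibble(
    person_id = c("A", "B"),
    protein_g = targets$mean[1] + c(-1, 1) * targets$sd[1],
    fiber_g = targets$mean[2] + c(-1, 1) * targets$sd[2],
    iron_mg = targets$mean[3] + c(-1, 1) * targets$sd[3],
    zinc_mg = targets$mean[4] + c(-1, 1) * targets$sd[4],
    calcium_mg = targets$mean[5] + c(-1, 1) * targets$sd[5],
    folate_dfe_ug = targets$mean[6] + c(-1, 1) * targets$sd[6],
    beef_serves_per_week = c(2, 3)
  )
  shifted <- apply_swap_to_cohort(cohort, swap, mode = "uniform")
  modeled <- summarize_cohort(shifted)
  expect_equal(round_half_up(modeled$mean[modeled$nutrient == "protein"], 1), 96.5)
  expect_equal(round_half_up(modeled$mean[modeled$nutrient == "zinc"], 1), 12.1)
  expect_equal(round_half_up(modeled$mean[modeled$nutrient == "calcium"], 1), 1026.2)
  expect_equal(round_half_up(modeled$mean[modeled$nutrient == "folate"], 1), 284.2)
  expect_equal(round_half_up(modeled$mean[modeled$nutrient == "iron"], 1), 14.3)
})

test_that("per-individual mode shifts only eligible records", {
  swap <- beef_tofu_swap()
  cohort <- toy_cohort()  # serves alternate 0, 2
  shifted <- apply_swap_to_cohort(cohort, swap, mode = "per_individual")
  eligible <- cohort$beef_serves_per_week >= 1
  expect_equal(shifted$swapped, eligible)
  expect_equal(shifted$zinc_mg[!eligible], cohort$zinc_mg[!eligible])
  expect_equal(shifted$zinc_mg[eligible],
               cohort$zinc_mg[eligible] + swap$nutrient_delta[["zinc_mg"]] / 7)

  # mean shift equals eligible fraction x delta/7 (linearity of the mean)
  f <- mean(eligible)
  expect_equal(mean(shifted$calcium_mg) - mean(cohort$calcium_mg),
               f * swap$nutrient_delta[["calcium_mg"]] / 7, tolerance = 1e-12)

  # the comparator is configurable: > 1 excludes exactly-one-serve records
  one_serve <- dplyr::mutate(cohort, beef_serves_per_week = 1)
  strict <- apply_swap_to_cohort(one_serve, swap, mode = "per_individual",
                                 comparator = ">")
  expect_false(any(strict$swapped))

  # both modes agree when everyone is eligible
  all_elig <- dplyr::mutate(cohort, beef_serves_per_week = 2)
  expect_equal(
    apply_swap_to_cohort(all_elig, swap, mode = "per_individual")$zinc_mg,
    apply_swap_to_cohort(all_elig, swap, mode = "uniform")$zinc_mg
  )
})

test_that("compliance is monotone in threshold and under positive shifts", {
  cohort <- generate_cohort(synthetic_cohort_config(n = 300, seed = 11))
  thresholds <- c(700, 840, 1000, 1200)
  counts <- vapply(thresholds, function(th) {
    nrvs <- tibble::tibble(nutrient = "calcium", kind = "EAR", threshold = th)
    nrv_compliance(cohort, nrvs)$n_met
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  swap <- beef_tofu_swap()  # calcium delta is positive
  after <- apply_swap_to_cohort(cohort, swap, mode = "uniform")
  nrvs <- nrv_pregnancy()
  expect_gte(
    nrv_compliance(after, nrvs)$n_met[nrvs$nutrient == "calcium"],
    nrv_compliance(cohort, nrvs)$n_met[nrvs$nutrient == "calcium"]
  )
})

test_that("cohort modeling requires a weekly scenario and valid records", {
  daily <- evaluate_swap(example_food_table(),
                         swap_scenario("Beef", "Tofu, firm", basis = "energy",
                                       frequency = "daily"))
  expect_error(apply_swap_to_cohort(toy_cohort(), daily),
               class = "sustainaswap_config_error")
  expect_error(validate_cohort(toy_cohort()[, -2]),
               class = "sustainaswap_schema_error")
  expect_error(validate_cohort(dplyr::mutate(toy_cohort(), iron_mg = -iron_mg)),
               class = "sustainaswap_validation_error")
  expect_error(summarize_cohort(toy_cohort()[0, ]),
               class = "sustainaswap_validation_error")
})

test_that("degenerate cohorts summarize sanely", {
  one <- toy_cohort()[1, ]
  expect_warning(s <- summarize_cohort(one), "single-record")
  expect_equal(s$sd, rep(0, nrow(s)))
  expect_equal(s$mean[s$nutrient == "protein"], one$protein_g)

  identical_records <- dplyr::bind_rows(one, one, one)
  s2 <- summarize_cohort(identical_records)
  expect_equal(s2$sd, rep(0, nrow(s2)))
  expect_equal(s2$q75 - s2$q25, rep(0, nrow(s2)))
})

test_that("cohort CSVs round-trip with a seed provenance comment", {
  cohort <- toy_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path, seed = 99)
  expect_match(readLines(path, n = 1), "seed 99")
  back <- load_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
})
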