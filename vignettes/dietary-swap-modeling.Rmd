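---
title: "Modeling sustainable food swaps during pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sustainable food swaps during pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustainaswap)
```

## The question the package answers

Food production is a major source of greenhouse-gas emissions, and beef is
the single largest contributor among commonly consumed foods. Yet animal
foods carry nutrients — iron, zinc, protein — whose requirements rise during
pregnancy, so advice to eat more sustainably meets the worry that doing so
risks nutritional inadequacy. `sustainaswap` models the *marginal* question:
if a pregnant woman on an ordinary mixed diet replaces one serve of beef per
week with an environmentally sustainable alternative of equal energy or
protein content, what happens to her nutrient intake, and how much
environmental impact is avoided over the 270 days of pregnancy?

## The substitution model

### Portion matching

Let the reference serve carry energy $E_{ref}$ (kJ) and protein $P_{ref}$
(g). An alternative food with per-serve energy $E_{alt}$ and protein
$P_{alt}$ is rescaled by

$$s = E_{ref}/E_{alt} \quad\text{(isoenergetic)}\qquad\text{or}\qquad
  s = P_{ref}/P_{alt} \quad\text{(protein-matched)},$$

and every nutrient, the cooked weight, and the retail (pre-cooking) weight
scale linearly with $s$. A third basis, `fixed`, keeps the alternative's own
standard serve and is meant for like-for-like daily swaps (milk for soy
milk). Matching is exact in floating point; the model never rounds
portions to kitchen-realistic weights internally, because the published
serve weights it must reproduce are themselves rounded grams — rounding is
a reporting concern only.

```{r matching}
tab <- example_food_table()
beef <- food_item(tab, "Beef")
isoenergetic_serve(food_item(tab, "Tofu, firm"), beef)[
  , c("name", "scale", "weight_cooked_g", "energy_kj", "protein_g")]
protein_matched_serve(food_item(tab, "Tofu, firm"), beef)[
  , c("name", "scale", "weight_cooked_g", "protein_g")]
```

### Estimated absorbed iron

Plant iron is entirely non-heme; iron in animal foods is modeled as 40%
heme and 60% non-heme. Within a mixed diet, 16.8% of non-heme and 25% of
heme iron are absorbed, giving effective multipliers of 0.168 (plant) and
$0.6 \times 0.168 + 0.4 \times 0.25 = 0.2008$ (animal). All three
proportions are arguments of `iron_absorption_params()` because the default
is deliberately conservative: non-heme absorption is up-regulated during
pregnancy, so the plant-food estimates err low. The model does not attempt
enhancer/inhibitor corrections (vitamin C, the meat factor); those
interactions are real but not quantified here.

### Environmental footprint

Five metrics are tracked per kilogram of retail weight: greenhouse-gas
emissions (kg CO₂ eq), land use (m²·yr), acidifying emissions (g SO₂ eq),
eutrophying emissions (g PO₄³⁻ eq), and stress-weighted water use (L), all
global mean life-cycle values. A serve's footprint is intensity × retail
weight; a weekly habit over a pregnancy of $D$ days accumulates $D/7$
serves ($270/7 \approx 38.57$ — kept fractional, since truncating to whole
weeks would understate every total by about 1.5%). GHG masses are also
expressed as kilometres of average passenger-vehicle driving via a fixed
factor of 0.400 kg CO₂ eq per mile (1.60934 km per mile). The factor is a
package constant chosen to be consistent, within ±1 km, with every
published (kg, km) pair the model is checked against; because the source of
such factors is a calculator rather than a printed number, whole-km
agreement to better than ±1 km is not forced.

```{r footprint}
res <- evaluate_swap(tab, swap_scenario("Beef", "Tofu, firm", basis = "energy"))
round_half_up(res$footprint_delta_pregnancy, 1)
res$km_equivalent
```

### Cohort modeling

A swap evaluated per serve becomes a daily intake shift $\Delta/7$ for a
weekly habit. Two application modes are exposed deliberately:

* `per_individual` (default): only records meeting the eligibility rule —
  at least `min_serves` (default 1) reference serves per week — are
  shifted. This is the realistic mode: a woman who never eats beef cannot
  swap it. The mean intake then shifts by (eligible fraction) × $\Delta/7$.
* `uniform`: every record is shifted. This reproduces analyses that shift
  whole summary tables by a constant — recognisable by modeled SD and IQR
  widths identical to the originals — and is retained so those published
  summaries can be recomputed exactly.

The eligibility comparator defaults to `>=` rather than `>`: "consuming at
least one serve a week" is the natural reading of eligibility for a weekly
swap, and the observed 65.5% eligible fraction is treated as an empirical
quantity, not a definition. The comparator is an argument for users who
prefer the strict reading.

A record meets a Nutrient Reference Value when its daily intake is at or
above the threshold. Adequate Intakes (fiber) are applied with the same
rule as Estimated Average Requirements: a population-level "meets the AI"
count is the convention the modeled tables use, even though AI and EAR have
different derivations. Iodine and saturated fat carry no threshold in the
default NRV set; they flow through swap deltas only.

## The synthetic cohort

Individual-level dietary data from pregnancy cohorts are almost never
shareable. The generator produces cohorts with the statistical structure
the downstream analysis assumes, so every stage stays testable:

* **Log-normal marginals**, moment-matched to target means and SDs
  ($\sigma^2_{\log} = \log(1 + (\mathrm{sd}/\mathrm{mean})^2)$,
  $\mu_{\log} = \log(\mathrm{mean}) - \sigma^2_{\log}/2$). Log-normality
  captures the right skew characteristic of FFQ-derived intakes: generated
  medians fall below means for every nutrient, as observed in real data.
* **A Gaussian copula** with exchangeable correlation, default
  $\rho = 0.3$. Within-person nutrient intakes are positively correlated
  (they share a common "eats more of everything" factor), but the true
  correlation structure is unknowable from summary tables; 0.3 is a
  plausible middling value and is fully configurable, including as a full
  correlation matrix.
* **Zero-inflated Poisson** weekly beef serves with $\lambda = 2$ among
  consumers (a realistic red-meat frequency); the inflation mass is solved
  so that $P(\text{serves} \ge 1)$ equals the configured eligible fraction,
  default 0.655. Only eligibility matters downstream, so $\lambda$ is a
  nuisance parameter.

Defaults emulate a cohort of 171 pregnant women with the intake means and
SDs of the population the package models. What the generator does *not*
emulate: food-level intakes (it draws nutrient totals directly), reporting
error and FFQ measurement bias, intra-nutrient dependence beyond a single
exchangeable coefficient, and any mean–variance relationship across
subgroups. Passing tests therefore demonstrate the *model's* internal
consistency — parameter recovery, shift linearity, compliance counting —
not agreement with any particular real cohort's medians or compliance
counts, which depend on the unavailable raw data.

```{r cohort}
cohort <- generate_cohort(synthetic_cohort_config(n = 171, seed = 1))
recover_parameters(cohort)$moments
```

## Numerical and design choices

* **Rounding** is half-away-from-zero (`round_half_up()`), applied only at
  report time: nutrients to 1 decimal, absorbed iron to 2, footprints to 1,
  vehicle distance to whole km. Internals are never rounded. Base `round()`
  (half-to-even) would disagree with published tables on .5 boundaries.
* **Quantiles** use linear interpolation between order statistics
  (`quantile()` type 7), stated so IQR columns are reproducible.
* **Ranking** of intake contributors is a stable descending sort: ties keep
  input order.
* **Retail serve weights** in the bundled table are derived, not measured:
  per-pregnancy GHG of one weekly serve ÷ (270/7) ÷ the food's per-kg GHG
  intensity (beef: 0.100 kg). This is the unique factorization consistent
  with the published footprint totals given the published intensities; see
  `inst/extdata/README.md`. Only the product intensity × retail weight
  enters any result, so the factorization cannot bias downstream numbers.
* **Per-serve nutrient values** come from published 1-dp serve tables
  rather than a food-composition database; recomputing derived cells (such
  as absorbed iron) from 1-dp inputs can land one printed unit away from
  values published from unrounded sources. The package reports its own
  arithmetic and flags, rather than forces, such cells; its absorbed-iron
  delta for the beef→tofu swap is +1.0 mg/serve iron by table arithmetic
  (2.7 − 1.7), not a separately published +1.1.
* **Degenerate inputs**: a single-record cohort reports SD 0 with a
  warning; identical records give zero SD and zero IQR width; an empty
  cohort, a zero-energy alternative under energy matching, a non-PSD
  correlation matrix, and a non-positive NRV threshold are errors. A swap
  that *increases* GHG reports 0 equivalent km with a warning instead of a
  negative distance.
* **Determinism**: `run_pipeline()` writes byte-identical reports for
  identical configuration and seed; generated cohorts are a pure function
  of their config.

## Problem sizes

The test-suite checks run at the sizes the properties need and no more:
moment recovery at n = 100 000 (means within 1%, SDs within 3%),
per-individual shift linearity at n = 10 000 (within 3 standard errors of
the eligible-fraction prediction), study-scale checks at n = 171, and
exhaustive compliance oracles on 4- and 10-record cohorts. The whole suite
runs in well under a minute.

## Known limitations

* Single-food, single-swap scenarios only: no diet-level optimization, no
  simultaneous energy-and-protein matching, no food–food absorption
  interactions.
* Environmental intensities are global means without uncertainty; no
  propagation of intensity distributions is attempted.
* The synthetic cohort is a modeling device; NRV compliance counts and
  medians computed from it are not estimates of any real cohort's values.
* Marginals are log-normal only; a gamma alternative would be a natural
  extension for sensitivity analysis but is not currently implemented.
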