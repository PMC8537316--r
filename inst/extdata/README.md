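# Bundled fixtures

## beef_alternatives.csv

Food-composition and environmental-intensity table for beef and thirteen
lower-emission alternatives. One row per food; every per-serve nutrient
profile is the isoenergetic serve matched to the 471 kJ standard cooked beef
serve, so `energy_kj` is 471 throughout and `serve_weight_cooked_g` is the
cooked weight of that isoenergetic serve.

Environmental intensities are global mean life-cycle values per kilogram of
retail (pre-cooking) weight. Retail serve weights are not published at serve
level; they are derived per food as

    serve_weight_retail_kg = (per-pregnancy GHG of one weekly serve / (270/7))
                             / ghg_kgco2e_per_kg

with per-kilogram GHG intensities from the Poore & Nemecek global means
(beef 99.5, chicken 9.9, fish 13.6, pork 12.3, lamb 39.7, egg 4.67,
pulses 1.79, tofu 3.16). Mixed nuts instead pin the retail weight to the
18 g serve and derive the intensity, because the land-use-credited published
nut intensity implies an implausible retail weight. The remaining
intensities (land, acidifying, eutrophying, stress-weighted water) are
derived from the per-pregnancy footprint of one weekly serve divided by
(270/7) and by the retail weight, so footprints recomputed from this table
reproduce the published per-serve and per-pregnancy values at reporting
precision by construction. See `data-raw/make_fixture.R` for the script.

Values are stored unrounded (6-8 significant digits); all rounding happens
at report time.

## nrv_pregnancy.csv

Nutrient Reference Values used for compliance modeling during pregnancy:
Estimated Average Requirements for protein (49 g/day), iron (22 mg),
zinc (9.0 mg), calcium (840 mg) and dietary folate equivalents (520 ug),
and the Adequate Intake for dietary fiber (28 g).
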