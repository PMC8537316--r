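name,origin,serve_weight_cooked_g,serve_weight_retail_kg,energy_kj,protein_g,sfa_g,fiber_g,iron_mg,zinc_mg,calcium_mg,iodine_ug,folate_dfe_ug,ghg_kgco2e_per_kg,land_m2_per_kg,acid_gso2e_per_kg,eutroph_gpo4e_per_kg,water_l_per_kg
Beef,animal,65,0.100004,471,20.2,1.2,0,1.7,5.1,5.2,1.1,0,99.5,326.18695,318.79836,301.37683,34731.107
Pork,animal,83,0.115507,471,23.7,0.6,0,0.8,2,3.3,0.7,36.6,12.3,17.39513,142.66251,76.381454,66851.773
Lamb,animal,49,0.0687004,471,14.2,2.5,0,1.1,2.1,4.5,0.2,7.9,39.7,369.90458,139.02555,97.136746,141970.07
Chicken,animal,74,0.0924429,471,21.4,0.9,0,0.4,0.6,6.7,0.4,2.2,9.9,12.199723,102.33745,48.658665,14168.254
Egg,animal,81,0.0810532,471,10,2.1,0,1.3,1,31.5,38.2,67,4.67,6.2693163,53.481106,21.718703,17908.782
Salmon,animal,39,0.0449891,471,11.4,1.6,0,0.6,0.2,3.9,3.8,0,13.6,8.4135606,65.925434,235.17631,41582.294
White fish,animal,89,0.102369,471,23.4,0.5,0,0.5,0.6,38.3,39.6,1.8,13.6,8.4082168,65.948784,235.27811,41605.097
"Beans, mixed",plant,110,0.111525,471,7.1,0.1,6.8,2.2,0.9,47.5,0.6,74,1.79,15.459082,21.898428,16.946873,22264.774
Chickpeas,plant,101,0.101386,471,6.4,0.2,4.7,1.8,1,45.4,0.5,63.6,1.79,15.547475,22.017066,17.030622,22389.617
Lentils,plant,133,0.133251,471,9,0.1,4.9,2.7,1.2,22.6,0.7,26.6,1.79,15.565167,22.044168,17.063314,22424.931
Baked beans,plant,133,0.133251,471,6.5,0.1,6.9,1.3,0.7,51.7,2,66.3,1.79,15.526254,21.985798,17.004945,22360.841
"Tofu, firm",plant,94,0.0951711,471,11.3,0.9,3.3,2.7,1.6,300,2.7,28.1,3.16,3.4596559,6.5924152,6.1020703,5036.8504
"Tofu, silken",plant,210,0.212494,471,11.3,0.7,4.8,3.8,1.1,50.4,2.5,27.3,3.16,3.4650216,6.6250237,6.1247917,5055.3323
Mixed nuts,plant,18,0.018,471,3.9,1.4,1.1,0.5,0.7,16.2,0.1,10.2,1.7283951,10.946502,33.559671,16.419753,144304.57
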