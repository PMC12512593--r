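category,subcategory,tree_ha_baseline,tree_ha_scenario,tree_ha_delta
age,<18,4.72,5.01,0.28
age,18-64,4.52,4.93,0.41
age,>=65,4.73,5.10,0.38
citizenship,citizen,4.63,5.02,0.39
citizenship,non_citizen,4.42,4.75,0.34
education,primary,4.59,4.84,0.25
education,secondary,4.74,5.01,0.27
education,tertiary,4.47,5.01,0.54
employment,unemployed,4.48,4.85,0.36
employment,employed,4.52,4.95,0.44
income,bottom_quintile,4.55,4.66,0.12
income,middle_quintiles,4.57,4.96,0.39
income,top_quintile,4.69,5.42,0.73
total,total,4.60,4.98,0.38
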