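category,subcategory,tree_ha_baseline,tree_ha_scenario,tree_ha_delta
age,<18,3.22,3.52,0.30
age,18-64,2.99,3.49,0.50
age,>=65,3.22,3.52,0.31
citizenship,citizen,3.06,3.50,0.44
citizenship,non_citizen,3.18,3.57,0.39
education,primary,3.18,3.55,0.37
education,secondary,3.06,3.52,0.45
education,tertiary,3.04,3.52,0.48
employment,unemployed,3.08,3.51,0.43
employment,employed,3.01,3.49,0.48
income,bottom_quintile,3.22,3.64,0.42
income,middle_quintiles,2.80,3.31,0.51
income,top_quintile,3.70,3.88,0.18
total,total,3.07,3.50,0.43
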