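category,subcategory,pm25_baseline,pm25_scenario,pm25_delta
age,<18,10.61,10.58,-0.028
age,18-64,10.65,10.61,-0.038
age,>=65,10.65,10.62,-0.030
citizenship,citizen,10.65,10.61,-0.035
citizenship,non_citizen,10.58,10.55,-0.034
education,primary,10.61,10.58,-0.033
education,secondary,10.64,10.60,-0.036
education,tertiary,10.66,10.63,-0.038
employment,unemployed,10.63,10.60,-0.036
employment,employed,10.65,10.62,-0.036
income,bottom_quintile,10.57,10.53,-0.042
income,middle_quintiles,10.67,10.64,-0.034
income,top_quintile,10.69,10.67,-0.020
total,total,10.64,10.61,-0.035
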