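category,subcategory,pm25_baseline,pm25_scenario,pm25_delta
age,<18,15.28,15.18,-0.099
age,18-64,15.32,15.18,-0.136
age,>=65,15.28,15.14,-0.133
citizenship,citizen,15.29,15.16,-0.130
citizenship,non_citizen,15.38,15.27,-0.113
education,primary,15.34,15.25,-0.093
education,secondary,15.28,15.18,-0.098
education,tertiary,15.31,15.14,-0.169
employment,unemployed,15.35,15.23,-0.124
employment,employed,15.31,15.17,-0.140
income,bottom_quintile,15.46,15.41,-0.059
income,middle_quintiles,15.22,15.09,-0.132
income,top_quintile,15.33,15.11,-0.211
total,total,15.30,15.18,-0.127
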