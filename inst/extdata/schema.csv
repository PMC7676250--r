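kind,column,unit
income,country,ISO3-style identifier
income,year,calendar year (5-year grid 1965-2100)
income,income,USD2005 PPP per capita per year
population,country,ISO3-style identifier
population,year,calendar year (5-year grid 1965-2100)
population,age,5-year age cohort (0-4 ... 95-99 or 100+)
population,sex,male or female
population,population,persons
height,country,ISO3-style identifier
height,year,calendar year (5-year grid 1965-2100)
height,age,5-year age cohort
height,sex,male or female
height,height_cm,cm
bmi_shares,country,ISO3-style identifier
bmi_shares,year,calendar year (5-year grid 1965-2100)
bmi_shares,age_group,0-14 or 15-59 or 60+
bmi_shares,sex,male or female
bmi_shares,bmi_class,BMI class label (adult kg/m2 bands or child z-score bands)
bmi_shares,share,population share in [0 and 1] summing to 1 per stratum
demand,country,ISO3-style identifier
demand,year,calendar year (5-year grid 1965-2100)
demand,demand_kcal,kcal per capita per day
composition,country,ISO3-style identifier
composition,year,calendar year (5-year grid 1965-2100)
composition,animal_kcal,kcal per capita per day
composition,empty_kcal,kcal per capita per day
composition,fvn_kcal,kcal per capita per day
composition,staple_kcal,kcal per capita per day
composition,total_kcal,kcal per capita per day (sum of the four groups)
diet_quality,country,ISO3-style identifier
diet_quality,year,calendar year (5-year grid 1965-2100)
diet_quality,g_kcal,kcal per capita per day (animal-source plus empty-calorie demand)
growth_standard,age,years (0-18)
growth_standard,sex,male or female
growth_standard,height_cm,reference median height in cm
growth_standard,median_bmi,reference median BMI in kg/m2
schofield,bracket,Schofield age bracket (0-3 3-10 10-18 18-30 30-60 60+)
schofield,sex,male or female
schofield,gamma_kcal_per_kg,kcal per day per kg body weight
schofield,delta_kcal,kcal per day intercept
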