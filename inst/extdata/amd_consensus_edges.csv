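source,target,weight
abandoned_farming,human_migration,0.560000
abandoned_farming,income_reduction,0.520000
abandoned_fishing,alternative_livelihoods,0.600000
abandoned_fishing,diarrhoea,0.480000
acid_pollution,abandoned_farming,1.000000
acid_pollution,abandoned_fishing,1.000000
acid_pollution,contaminated_fish,0.980000
acid_pollution,crop_yield_reduction,0.980000
acid_pollution,diarrhoea,1.000000
acid_pollution,family_relocation,0.760000
acid_pollution,fish_catch_reduction,0.980000
acid_pollution,fish_population_decrease,0.960000
acid_pollution,fishing_festivals,0.720000
acid_pollution,foul_smell,0.960000
acid_pollution,human_mortality,1.000000
acid_pollution,income_reduction,0.720000
acid_pollution,livestock_mortality,0.960000
acid_pollution,poor_water_quality,0.960000
acid_pollution,restoration_expenditure,0.680000
acid_pollution,seeking_medical_care,0.980000
acid_pollution,skin_diseases,0.740000
acid_pollution,traditional_healing,0.720000
acid_pollution,vegetation_mortality,0.980000
acid_pollution,water_colour_changes,0.960000
acid_pollution,water_purification,1.000000
contaminated_fish,alternative_livelihoods,1.000000
contaminated_fish,income_reduction,0.740000
crop_yield_reduction,traditional_farming,0.920000
fish_catch_reduction,traditional_fishing,0.920000
lime_expenditure,acid_pollution,-0.800000
peoples_awareness,livelihood_suspension,-0.920000
poor_water_quality,advocacy_legal_action,0.680000
poor_water_quality,alternative_water_sources,0.800000
poor_water_quality,authority_restrictions,0.840000
poor_water_quality,income_reduction,0.780000
poor_water_quality,livelihood_suspension,1.000000
poor_water_quality,religious_ceremonies,0.720000
poor_water_quality,school_absenteeism,0.740000
poor_water_quality,violent_conflict,0.740000
seeking_medical_care,spend_money,0.700000
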