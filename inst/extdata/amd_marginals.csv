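id,label,indegree,outdegree,type
acid_pollution,Acid pollution,0.80,19.04,ordinary
poor_water_quality,Poor water quality,0.96,6.30,ordinary
income_reduction,Income reduction,2.76,0.00,receiver
contaminated_fish,Contaminated fish,0.98,1.74,ordinary
abandoned_fishing,Abandoned fishing,1.00,1.08,ordinary
abandoned_farming,Abandoned farming,1.00,1.08,ordinary
livelihood_suspension,Livelihood activity suspension,1.92,0.00,receiver
fish_catch_reduction,Fish catch reduction,0.98,0.92,ordinary
crop_yield_reduction,Crop yield reduction,0.98,0.92,ordinary
seeking_medical_care,Seeking medical care,0.98,0.70,ordinary
alternative_livelihoods,Alternative livelihoods,1.60,0.00,receiver
diarrhoea,Diarrhoea,1.48,0.00,receiver
water_purification,Water purification methods,1.00,0.00,receiver
human_mortality,Human mortality,1.00,0.00,receiver
vegetation_mortality,Vegetation mortality,0.98,0.00,receiver
livestock_mortality,Livestock mortality,0.96,0.00,receiver
fish_population_decrease,Fish population decrease,0.96,0.00,receiver
foul_smell,Foul smell,0.96,0.00,receiver
water_colour_changes,Water colour changes,0.96,0.00,receiver
peoples_awareness,People's awareness,0.00,0.92,driver
traditional_farming,Traditional farming practices,0.92,0.00,receiver
traditional_fishing,Traditional fishing,0.92,0.00,receiver
authority_restrictions,Local authority restrictions,0.84,0.00,receiver
alternative_water_sources,Alternative water sources,0.80,0.00,receiver
lime_expenditure,Lime expenditure,0.00,0.80,driver
family_relocation,Family relocation,0.76,0.00,receiver
violent_conflict,Violent conflict,0.74,0.00,receiver
school_absenteeism,Pupil school absenteeism,0.74,0.00,receiver
skin_diseases,Skin diseases,0.74,0.00,receiver
traditional_healing,Traditional healing practices,0.72,0.00,receiver
fishing_festivals,Fishing festivals,0.72,0.00,receiver
religious_ceremonies,Religious ceremonies,0.72,0.00,receiver
spend_money,Spend money,0.70,0.00,receiver
advocacy_legal_action,Advocacy/legal action,0.68,0.00,receiver
restoration_expenditure,Restoration expenditure,0.68,0.00,receiver
human_migration,Human migration,0.56,0.00,receiver
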