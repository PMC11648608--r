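id,name,category,serving_g,variant,ghg_kg_per_kg,land_m2_per_kg,water_l_per_kg,ghg_processing_kg_per_kg,price,currency,year,energy_kcal,protein_g,fat_g,carbohydrate_g,sugar_g,fiber_g,satfat_g,mufa_g,pufa_g,transfat_g,cholesterol_mg,calcium_mg,iron_mg,heme_iron_mg,magnesium_mg,phosphorus_mg,phytate_mg,potassium_mg,sodium_mg,zinc_mg,copper_mg,vitamin_c_mg,thiamine_mg,riboflavin_mg,niacin_mg,pantothenate_mg,vitamin_b6_mg,folate_ug,vitamin_b12_ug,vitamin_a_ug
beef,beef,meat,110,NA,57.36869864957541,162.57213895448285,1399.9077474658147,0,10.483458164620197,USD,2020,242.29069573813732,24.22906957381373,16.475767310193337,0,0,0,6.784139480667845,7.26872087214412,0.5814976697715296,0.2907488348857648,85.28632489982434,14.53744174428824,2.519823235676628,1.7444930093145887,21.321581224956084,193.83255659050985,0,310.1320905448158,63.96474367486825,6.008809254305806,0.07753302263620394,0,0.06784139480667846,0.17444930093145888,4.845813914762747,0.5814976697715296,0.38766511318101976,7.7533022636203945,2.519823235676628,4.845813914762747
whole_milk,whole milk,dairy,240,NA,3.3153014222260726,8.602865568067351,632.6572552505556,0,1.1047080217958536,USD,2020,62.50492269712712,3.2789467644394557,3.3814138508281886,4.918420146659183,5.1233543194366495,0,1.9468746413859266,0.8197366911098639,0.20493417277746598,0.10246708638873299,10.246708638873299,122.96050366647958,0.030740125916619895,0,11.27137950276063,97.34373206929634,0,143.45392094422618,45.08551801104252,0.40986834555493196,0.010246708638873298,0,0.04098683455549319,0.17419404686084608,0.10246708638873299,0.37912821963831206,0.04098683455549319,5.1233543194366495,0.5123354319436649,47.13485973881718
soybeans,soybeans,unprocessed_alternative,45,NA,0.9016127455580427,2.1798352221766217,36.34511216665327,0.6,3.097944011091061,USD,2020,178.21492176473112,18.86981524567741,9.434907622838706,10.483230692043007,2.0966461384086013,6.289938415225803,1.3628199899655908,2.0966461384086013,5.346447652941933,0,0,62.89938415225804,5.346447652941933,0,73.38261484430105,188.69815245677412,628.9938415225804,545.1279959862363,1.0483230692043006,1.2579876830451606,0.3669130742215052,1.5724846038064508,0.20966461384086013,0.30401369006924717,1.2579876830451606,0.5241615346021503,0.20966461384086013,115.31553761247307,0,1.0483230692043006
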