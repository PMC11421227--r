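nutrient,age_lo,age_hi,sex,ear,ear_basis,ul,amdr_lo,amdr_hi,eer,rni,conversion_factor
energy,5,5,M,,,,,,1467,,
energy,6,6,M,,,,,,1573,,
energy,7,7,M,,,,,,1692,,
energy,8,8,M,,,,,,1830,,
energy,9,9,M,,,,,,1978,,
energy,5,5,F,,,,,,1330,,
energy,6,6,F,,,,,,1428,,
energy,7,7,F,,,,,,1554,,
energy,8,8,F,,,,,,1698,,
energy,9,9,F,,,,,,1854,,
protein,5,8,all,0.76,g_per_kg,,10,30,,,
protein,9,9,all,0.76,g_per_kg,,10,30,,,
carbohydrate,5,8,all,100,absolute,,45,65,,,
carbohydrate,9,9,all,100,absolute,,45,65,,,
fat,5,8,all,,,,25,35,,,
fat,9,9,all,,,,25,35,,,
sfa,5,8,all,,,,,,,,
sfa,9,9,all,,,,,,,,
mufa,5,8,all,,,,,,,,
mufa,9,9,all,,,,,,,,
pufa,5,8,all,,,,,,,,
pufa,9,9,all,,,,,,,,
calcium,5,8,all,800,absolute,2500,,,,,
calcium,9,9,all,1100,absolute,3000,,,,,
phosphorus,5,8,all,405,absolute,3000,,,,,
phosphorus,9,9,all,1055,absolute,4000,,,,,
iron,5,6,all,,,40,,,,12.6,
iron,7,9,all,,,40,,,,17.8,
zinc,5,6,all,,absolute,12,,,,9.6,1.2
zinc,7,9,all,,absolute,23,,,,11.2,1.2
vitamin_a,5,8,all,275,absolute,900,,,,,
vitamin_a,9,9,F,420,absolute,1700,,,,,
vitamin_a,9,9,M,445,absolute,1700,,,,,
vitamin_d,5,8,all,10,absolute,75,,,,,
vitamin_d,9,9,all,10,absolute,100,,,,,
vitamin_c,5,8,all,22,absolute,650,,,,,
vitamin_c,9,9,all,39,absolute,1200,,,,,
thiamin,5,8,all,0.5,absolute,,,,,,
thiamin,9,9,all,0.7,absolute,,,,,,
riboflavin,5,8,all,0.5,absolute,,,,,,
riboflavin,9,9,all,0.8,absolute,,,,,,
niacin,5,8,all,6,absolute,15,,,,,
niacin,9,9,all,9,absolute,20,,,,,
vitamin_b6,5,8,all,0.5,absolute,40,,,,,
vitamin_b6,9,9,all,0.8,absolute,60,,,,,
folate,5,8,all,160,absolute,400,,,,,
folate,9,9,all,250,absolute,600,,,,,
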