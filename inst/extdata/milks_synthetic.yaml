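# Default milk compositions per 100 g edible portion.
#
# SYNTHETIC DEFAULTS: these values are drawn from standard food-composition
# sources (USDA-style whole-milk entries; a typical reconstituted fortified
# filled-milk powder) and are NOT survey-verbatim. Override with your own
# file via load_milks(path).
#
# Units match nutrient_names(): energy kcal; protein/carbohydrate/fat/
# sfa/mufa/pufa g; calcium/phosphorus/iron/zinc/vitamin_c/thiamin/
# riboflavin/niacin/vitamin_b6 mg; vitamin_a ug RAE; vitamin_d ug;
# folate ug DFE. retinol_fraction is the preformed-retinol share of
# vitamin A RAE; folic_acid_fraction the synthetic share of folate DFE.
buffalo:
  energy: 97
  protein: 3.75
  carbohydrate: 5.18
  fat: 6.89
  sfa: 4.6
  mufa: 1.8
  pufa: 0.15
  calcium: 169
  phosphorus: 117
  iron: 0.12
  zinc: 0.22
  vitamin_a: 53
  vitamin_d: 0.0
  vitamin_c: 2.3
  thiamin: 0.052
  riboflavin: 0.135
  niacin: 0.091
  vitamin_b6: 0.023
  folate: 6
  retinol_fraction: 1.0
  folic_acid_fraction: 0.0
cow:
  energy: 61
  protein: 3.15
  carbohydrate: 4.8
  fat: 3.25
  sfa: 1.87
  mufa: 0.81
  pufa: 0.2
  calcium: 113
  phosphorus: 84
  iron: 0.03
  zinc: 0.37
  vitamin_a: 46
  vitamin_d: 0.1
  vitamin_c: 0.0
  thiamin: 0.046
  riboflavin: 0.169
  niacin: 0.089
  vitamin_b6: 0.036
  folate: 5
  retinol_fraction: 1.0
  folic_acid_fraction: 0.0
goat:
  energy: 69
  protein: 3.56
  carbohydrate: 4.45
  fat: 4.14
  sfa: 2.67
  mufa: 1.11
  pufa: 0.15
  calcium: 134
  phosphorus: 111
  iron: 0.05
  zinc: 0.3
  vitamin_a: 57
  vitamin_d: 0.1
  vitamin_c: 1.3
  thiamin: 0.048
  riboflavin: 0.138
  niacin: 0.277
  vitamin_b6: 0.046
  folate: 1
  retinol_fraction: 1.0
  folic_acid_fraction: 0.0
fortified:
  energy: 70
  protein: 2.8
  carbohydrate: 8.5
  fat: 2.8
  sfa: 1.0
  mufa: 1.0
  pufa: 0.7
  calcium: 175
  phosphorus: 80
  iron: 1.5
  zinc: 0.6
  vitamin_a: 60
  vitamin_d: 1.0
  vitamin_c: 12
  thiamin: 0.10
  riboflavin: 0.15
  niacin: 0.8
  vitamin_b6: 0.10
  folate: 10
  retinol_fraction: 1.0
  folic_acid_fraction: 0.8
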