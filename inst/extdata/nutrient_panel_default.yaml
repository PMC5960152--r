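nutrients:
  energy: kcal
  protein: g
  carbohydrate: g
  total_fat: g
  saturated_fat: g
  vitamin_a: ug_rae
  vitamin_c: mg
  vitamin_d: ug
  vitamin_e: mg
  thiamin: mg
  riboflavin: mg
  niacin: mg
  vitamin_b6: mg
  folate: ug_dfe
  vitamin_b12: ug
  calcium: mg
  iron: mg
  magnesium: mg
  sodium: mg
  zinc: mg
  fiber: g
  epa: g
  dha: g
  alpha_linolenic_acid: g
  vitamin_k: ug
  choline: mg
  potassium: mg
  alpha_carotene: ug
  beta_carotene: ug
  beta_cryptoxanthin: ug
  lutein_zeaxanthin: ug
  lycopene: ug
reverse:
- sodium
- saturated_fat
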