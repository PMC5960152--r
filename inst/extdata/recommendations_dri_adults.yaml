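- nutrient: vitamin_a
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: Inf
  threshold: 625.0
- nutrient: vitamin_a
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: Inf
  threshold: 500.0
- nutrient: vitamin_c
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: Inf
  threshold: 75.0
- nutrient: vitamin_c
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: Inf
  threshold: 60.0
- nutrient: vitamin_d
  rule: EAR_below
  sex: all
  age_min: 19.0
  age_max: Inf
  threshold: 10.0
- nutrient: vitamin_e
  rule: EAR_below
  sex: all
  age_min: 19.0
  age_max: Inf
  threshold: 12.0
- nutrient: thiamin
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: Inf
  threshold: 1.0
- nutrient: thiamin
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: Inf
  threshold: 0.9
- nutrient: riboflavin
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: Inf
  threshold: 1.1
- nutrient: riboflavin
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: Inf
  threshold: 0.9
- nutrient: niacin
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: Inf
  threshold: 12.0
- nutrient: niacin
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: Inf
  threshold: 11.0
- nutrient: vitamin_b6
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: 50.0
  threshold: 1.1
- nutrient: vitamin_b6
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: 50.0
  threshold: 1.0
- nutrient: vitamin_b6
  rule: EAR_below
  sex: male
  age_min: 51.0
  age_max: Inf
  threshold: 1.4
- nutrient: vitamin_b6
  rule: EAR_below
  sex: female
  age_min: 51.0
  age_max: Inf
  threshold: 1.3
- nutrient: folate
  rule: EAR_below
  sex: all
  age_min: 19.0
  age_max: Inf
  threshold: 320.0
- nutrient: vitamin_b12
  rule: EAR_below
  sex: all
  age_min: 19.0
  age_max: Inf
  threshold: 2.0
- nutrient: calcium
  rule: EAR_below
  sex: all
  age_min: 19.0
  age_max: 50.0
  threshold: 800.0
- nutrient: calcium
  rule: EAR_below
  sex: male
  age_min: 51.0
  age_max: 70.0
  threshold: 800.0
- nutrient: calcium
  rule: EAR_below
  sex: female
  age_min: 51.0
  age_max: 70.0
  threshold: 1000.0
- nutrient: calcium
  rule: EAR_below
  sex: all
  age_min: 71.0
  age_max: Inf
  threshold: 1000.0
- nutrient: iron
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: Inf
  threshold: 6.0
- nutrient: iron
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: 50.0
  threshold: 8.1
- nutrient: iron
  rule: EAR_below
  sex: female
  age_min: 51.0
  age_max: Inf
  threshold: 5.0
- nutrient: magnesium
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: 30.0
  threshold: 330.0
- nutrient: magnesium
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: 30.0
  threshold: 255.0
- nutrient: magnesium
  rule: EAR_below
  sex: male
  age_min: 31.0
  age_max: Inf
  threshold: 350.0
- nutrient: magnesium
  rule: EAR_below
  sex: female
  age_min: 31.0
  age_max: Inf
  threshold: 265.0
- nutrient: zinc
  rule: EAR_below
  sex: male
  age_min: 19.0
  age_max: Inf
  threshold: 9.4
- nutrient: zinc
  rule: EAR_below
  sex: female
  age_min: 19.0
  age_max: Inf
  threshold: 6.8
- nutrient: sodium
  rule: UL_above
  sex: all
  age_min: 19.0
  age_max: Inf
  threshold: 2300.0
- nutrient: saturated_fat
  rule: PCT_ENERGY_above
  sex: all
  age_min: 19.0
  age_max: Inf
  threshold: 10.0
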