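{
  "name": "kalter",
  "label": "Kalter et al. 2015",
  "age_group": "child",
  "ranks": [
    ["injury"],
    ["aids"],
    ["malnutrition_underlying"],
    ["measles"],
    ["meningitis"],
    ["dysentery"],
    ["diarrhea"],
    ["pertussis"],
    ["pneumonia"],
    ["malaria"],
    ["possible_dysentery"],
    ["possible_diarrhea"],
    ["possible_pneumonia"],
    ["hemorrhagic_fever"],
    ["other_infection", "other_infectious"],
    ["residual_infection"],
    ["malnutrition"],
    ["non_infectious"]
  ],
  "fallback": "unspecified",
  "extended": ["other_infectious placed with other infection", "non_infectious appended as lowest rank"]
}
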