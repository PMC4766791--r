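{
  "name": "liu",
  "label": "Liu et al. 2015",
  "age_group": "child",
  "ranks": [
    ["injury"],
    ["measles", "diarrhea", "ari", "pneumonia"],
    ["meningitis"],
    ["malaria"],
    ["aids"],
    ["possible_diarrhea", "possible_ari", "possible_pneumonia"],
    ["other_possible_serious_infection", "other_infectious"],
    ["non_infectious"]
  ],
  "fallback": "unspecified",
  "extended": ["pneumonia placed with ARI", "other_infectious placed with other possible serious infections", "non_infectious appended as lowest rank"]
}
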