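{
  "name": "arifeen",
  "label": "Arifeen et al. 2004",
  "age_group": "child",
  "ranks": [
    ["injury"],
    ["ari", "pneumonia", "diarrhea", "measles"],
    ["possible_serious_infection", "meningitis", "malaria", "aids", "other_infectious"],
    ["malnutrition"],
    ["other", "non_infectious"]
  ],
  "fallback": "unspecified",
  "extended": ["pneumonia placed with ARI", "meningitis/malaria/aids/other_infectious placed in the possible-serious-infections rank", "non_infectious placed with other causes"]
}
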