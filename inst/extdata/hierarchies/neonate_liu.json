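{
  "name": "liu",
  "label": "Liu et al. 2015",
  "age_group": "neonate",
  "ranks": [
    ["neonatal_tetanus"],
    ["congenital_malformation"],
    ["birth_asphyxia", "birth_injury"],
    ["diarrhea", "ari", "pneumonia"],
    ["meningitis"],
    ["possible_pneumonia", "possible_diarrhea"],
    ["preterm_delivery"],
    ["sepsis", "other_possible_serious_infection"]
  ],
  "fallback": "unspecified",
  "extended": ["pneumonia placed with ARI"]
}
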