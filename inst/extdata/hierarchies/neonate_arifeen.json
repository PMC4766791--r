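{
  "name": "arifeen",
  "label": "Arifeen et al. 2004",
  "age_group": "neonate",
  "ranks": [
    ["neonatal_tetanus"],
    ["congenital_malformation"],
    ["birth_asphyxia"],
    ["birth_injury"],
    ["ari", "pneumonia", "diarrhea"],
    ["possible_diarrhea", "possible_ari", "possible_pneumonia", "sepsis", "meningitis"],
    ["preterm_delivery"],
    ["other"]
  ],
  "fallback": "unspecified",
  "extended": ["pneumonia placed with ARI", "possible_pneumonia placed with possible ARI", "meningitis placed in the serious-infection (sepsis) rank"]
}
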