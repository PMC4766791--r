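{
  "name": "baqui",
  "label": "Baqui et al. 2006",
  "age_group": "neonate",
  "ranks": [
    ["neonatal_tetanus", "congenital_malformation"],
    ["preterm_delivery"],
    ["birth_asphyxia"],
    ["birth_injury"],
    ["sepsis", "pneumonia", "meningitis"],
    ["diarrhea"]
  ],
  "fallback": "unspecified",
  "extended": ["meningitis placed in the 'sepsis or pneumonia' serious-infection rank"]
}
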