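{
  "name": "lawn",
  "label": "Lawn et al. 2006",
  "age_group": "neonate",
  "ranks": [
    ["congenital_malformation"],
    ["neonatal_tetanus"],
    ["preterm_delivery"],
    ["birth_asphyxia"],
    ["sepsis", "pneumonia", "meningitis"],
    ["diarrhea"],
    ["other"]
  ],
  "fallback": "unspecified",
  "extended": []
}
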