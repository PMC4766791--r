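{
  "name": "compromise",
  "label": "Compromise",
  "age_group": "neonate",
  "ranks": [
    ["congenital_malformation"],
    ["birth_asphyxia"],
    ["preterm_delivery"],
    ["sepsis", "pneumonia", "meningitis"]
  ],
  "fallback": "unspecified",
  "extended": []
}
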