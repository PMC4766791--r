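{
  "name": "kalter",
  "label": "Kalter et al. 2015",
  "age_group": "neonate",
  "ranks": [
    ["neonatal_tetanus"],
    ["congenital_malformation"],
    ["birth_asphyxia", "birth_injury"],
    ["meningitis"],
    ["diarrhea"],
    ["pneumonia"],
    ["possible_diarrhea"],
    ["possible_pneumonia"],
    ["sepsis"],
    ["jaundice"],
    ["hemorrhagic_disease"],
    ["sudden_unexplained_death"],
    ["preterm_delivery"]
  ],
  "fallback": "unspecified",
  "extended": []
}
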