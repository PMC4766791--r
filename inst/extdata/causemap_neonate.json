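{
  "age_group": "neonate",
  "direct": {
    "rds": "preterm_delivery",
    "preterm_with_rds": "preterm_delivery",
    "sepsis_with_local_infection": "sepsis"
  },
  "comorbid": [
    {"pattern": ["preterm_delivery", "birth_asphyxia"], "target": "birth_asphyxia"},
    {"pattern": ["preterm_delivery", "sepsis"], "target": "sepsis"},
    {"pattern": ["preterm_delivery", "sepsis", "birth_asphyxia"],
     "proportional": ["sepsis", "birth_asphyxia"]}
  ],
  "groups": {
    "possible_pneumonia": "pneumonia",
    "possible_ari": "pneumonia",
    "ari": "pneumonia"
  }
}
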