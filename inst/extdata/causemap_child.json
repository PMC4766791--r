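{
  "age_group": "child",
  "direct": {
    "encephalitis": "meningitis",
    "dysentery": "diarrhea",
    "animal_bite": "injury",
    "burn": "injury",
    "drowning": "injury",
    "fall": "injury",
    "poisoning": "injury",
    "road_traffic_injury": "injury",
    "violent_death": "injury",
    "hemorrhagic_fever": "other_infectious",
    "sepsis": "other_infectious",
    "tuberculosis": "other_infectious",
    "other_infections": "other_infectious"
  },
  "comorbid": [
    {"pattern": ["pneumonia", "diarrhea"], "proportional": ["pneumonia", "diarrhea"]}
  ],
  "groups": {
    "possible_pneumonia": "pneumonia",
    "possible_ari": "pneumonia",
    "ari": "pneumonia",
    "possible_diarrhea": "diarrhea",
    "possible_dysentery": "diarrhea",
    "dysentery": "diarrhea",
    "residual_infection": "malaria",
    "pertussis": "other_infectious",
    "hemorrhagic_fever": "other_infectious",
    "other_infection": "other_infectious"
  }
}
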