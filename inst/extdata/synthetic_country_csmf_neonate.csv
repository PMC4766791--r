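"country_id","age_group","u5mr","malaria_fraction","preterm_delivery","birth_asphyxia","congenital_malformation","meningitis","pneumonia","sepsis","neonatal_tetanus"
"SYN_N_01","neonate",120,0.18,0.376,0.164,0.057,0.062,0.096,0.16,0.085
"SYN_N_02","neonate",90,0.12,0.207,0.37,0.045,0.072,0.17,0.094,0.042
"SYN_N_03","neonate",75,0.01,0.252,0.283,0.051,0.022,0.04,0.301,0.051
"SYN_N_04","neonate",60,0.22,0.17,0.254,0.104,0.132,0.097,0.206,0.037
"SYN_N_05","neonate",45,0.03,0.314,0.184,0.067,0.073,0.138,0.155,0.069
"SYN_N_06","neonate",38,0.08,0.198,0.235,0.057,0.033,0.131,0.278,0.068
"SYN_N_07","neonate",33,0.02,0.327,0.167,0.033,0.063,0.067,0.297,0.046
"SYN_N_08","neonate",28,0.06,0.301,0.23,0.039,0.089,0.107,0.177,0.057
"SYN_N_09","neonate",22,0.01,0.333,0.233,0.02,0.062,0.083,0.2,0.069
"SYN_N_10","neonate",12,0,0.351,0.143,0.073,0.052,0.11,0.212,0.059
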