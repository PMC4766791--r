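"country_id","age_group","u5mr","malaria_fraction","pneumonia","diarrhea","malaria","aids","measles","meningitis","injury","other_infectious","non_infectious"
"SYN_C_01","child",120,0.18,0.135,0.151,0.192,0.035,0.032,0.072,0.102,0.16,0.121
"SYN_C_02","child",90,0.12,0.129,0.256,0.125,0.049,0.036,0.037,0.094,0.123,0.151
"SYN_C_03","child",75,0.01,0.289,0.221,0.011,0.044,0.052,0.101,0.056,0.107,0.119
"SYN_C_04","child",60,0.22,0.105,0.144,0.212,0.067,0.05,0.037,0.134,0.097,0.154
"SYN_C_05","child",45,0.03,0.217,0.193,0.042,0.066,0.05,0.079,0.085,0.148,0.12
"SYN_C_06","child",38,0.08,0.215,0.163,0.107,0.038,0.051,0.043,0.058,0.179,0.146
"SYN_C_07","child",33,0.02,0.232,0.16,0.026,0.029,0.03,0.074,0.114,0.137,0.198
"SYN_C_08","child",28,0.06,0.262,0.235,0.059,0.043,0.054,0.045,0.07,0.121,0.111
"SYN_C_09","child",22,0.01,0.197,0.183,0.013,0.085,0.039,0.06,0.118,0.112,0.193
"SYN_C_10","child",12,0,0.124,0.258,0.005,0.045,0.028,0.064,0.065,0.124,0.287
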