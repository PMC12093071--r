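variable,phase1,phase2,phase3,phase4,phase5
age_group,0,0,0,0,0
gender,0,0,0,0,0
education,0.009,0.009,0.009,0.009,0.009
fruit_veg,0.010,0.018,0.020,0.029,0.023
smoking,0.049,0.054,0.102,0.145,0.157
alcohol,0.043,0.036,0.038,0.030,0.047
ltpa,0.010,0.010,0.014,0.016,0.009
insomnia,0.083,0.084,0.091,0.143,0.116
bmi,0.012,0.011,0.015,0.013,0.015
hypertension,0.011,0.017,0.016,0.205,0.157
high_cholesterol,0.010,0.011,0.005,0.258,0.220
diabetes,0.120,0.225,0.215,0.318,0.317
mental_disorders,0.096,0.196,0.200,0.321,0.318
pain,0.023,0.031,0.024,0.049,0.040
concentration,1,1,1,0.017,0.017
memory,1,1,1,0.010,0.014
learning,1,1,1,0.017,0.016
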