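variable,category,phase1,phase2,phase3,phase4,phase5
age_group,40,0.201,0,0,0,0
age_group,45,0.212,0.191,0,0,0
age_group,50,0.217,0.204,0.183,0,0
age_group,55,0.249,0.217,0.205,0.193,0
age_group,60,0.121,0.260,0.220,0.214,0.204
age_group,65,0,0.127,0.266,0.222,0.227
age_group,70,0,0,0.127,0.255,0.222
age_group,75,0,0,0,0.116,0.244
age_group,80,0,0,0,0,0.103
gender,woman,0.800,0.800,0.800,0.800,0.800
gender,man,0.200,0.200,0.200,0.200,0.200
education,basic,0.427,0.427,0.427,0.427,0.427
education,secondary,0.315,0.315,0.315,0.315,0.315
education,higher,0.259,0.259,0.259,0.259,0.259
fruit_veg,both_daily,0.468,0.517,0.539,0.534,0.606
fruit_veg,either_daily,0.293,0.283,0.273,0.250,0.240
fruit_veg,nondaily,0.239,0.200,0.188,0.216,0.154
smoking,never,0.509,0.518,0.504,0.470,0.471
smoking,ex_smoker,0.243,0.293,0.341,0.390,0.428
smoking,current_smoker,0.248,0.189,0.155,0.140,0.101
alcohol,none,0.070,0.085,0.105,0.142,0.183
alcohol,moderate,0.765,0.726,0.735,0.719,0.716
alcohol,high,0.097,0.102,0.089,0.080,0.057
alcohol,very_high,0.067,0.088,0.071,0.059,0.044
ltpa,inactive,0.252,0.227,0.265,0.242,0.245
ltpa,active,0.748,0.773,0.735,0.758,0.755
insomnia,lt4_nights,0.491,0.427,0.442,0.427,0.424
insomnia,n4_14_nights,0.316,0.322,0.309,0.299,0.304
insomnia,gt14_nights,0.193,0.250,0.249,0.274,0.272
bmi,under_or_healthy,0.514,0.461,0.424,0.404,0.404
bmi,overweight,0.342,0.357,0.367,0.378,0.372
bmi,obesity,0.144,0.182,0.209,0.219,0.224
hypertension,no,0.771,0.671,0.614,0.485,0.402
hypertension,yes,0.229,0.329,0.386,0.515,0.598
high_cholesterol,no,0.788,0.652,0.568,0.540,0.438
high_cholesterol,yes,0.212,0.348,0.432,0.460,0.562
diabetes,no,0.970,0.932,0.886,0.828,0.794
diabetes,yes,0.030,0.068,0.114,0.172,0.206
mental_disorders,no,0.815,0.771,0.789,0.794,0.796
mental_disorders,yes,0.185,0.229,0.211,0.206,0.204
pain,no,0.554,0.553,0.577,0.563,0.557
pain,yes,0.446,0.447,0.423,0.437,0.443
concentration,good,0.695,0.695,0.695,0.695,0.690
concentration,declined,0.305,0.305,0.305,0.305,0.310
memory,good,0.676,0.676,0.676,0.676,0.686
memory,declined,0.324,0.324,0.324,0.324,0.314
learning,good,0.523,0.523,0.523,0.523,0.521
learning,declined,0.477,0.477,0.477,0.477,0.479
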