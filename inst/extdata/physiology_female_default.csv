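age_years,bw_kg,frac_plasma,frac_liver,frac_brain,frac_bone,frac_rest
0.00,3.5,0.350000000000000,0.0371428571428571,0.1057142857142857,0.100000000000000,0.380000000000000
0.25,5.6,0.319642857142857,0.0357142857142857,0.0982142857142857,0.100000000000000,0.419642857142857
0.50,7.2,0.300000000000000,0.0347222222222222,0.0902777777777778,0.104166666666667,0.440277777777778
1.00,9.0,0.270000000000000,0.0355555555555556,0.1055555555555556,0.105555555555556,0.470000000000000
2.00,11.5,0.250434782608696,0.0339130434782609,0.0956521739130435,0.104347826086957,0.500000000000000
5.00,18.0,0.230000000000000,0.0316666666666667,0.0694444444444444,0.105555555555556,0.540000000000000
10.00,32.0,0.220000000000000,0.0296875000000000,0.0406250000000000,0.107812500000000,0.559375000000000
13.00,46.0,0.210000000000000,0.0260869565217391,0.0284782608695652,0.110000000000000,0.569565217391304
16.00,54.0,0.210000000000000,0.0250000000000000,0.0242592592592593,0.110000000000000,0.579629629629630
20.00,58.0,0.200000000000000,0.0258620689655172,0.0225862068965517,0.112068965517241,0.600000000000000
30.00,60.0,0.200000000000000,0.0260000000000000,0.0218333333333333,0.113000000000000,0.600000000000000
40.00,60.0,0.200000000000000,0.0260000000000000,0.0218333333333333,0.113000000000000,0.600000000000000
50.00,60.0,0.200000000000000,0.0260000000000000,0.0218333333333333,0.113000000000000,0.600000000000000
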