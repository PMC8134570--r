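energy_keV,mu_over_rho_cm2_g
10,120.0
15,115.0
20,55.60
30,18.90
40,8.600
50,4.750
60,2.920
65.34,2.320
65.36,10.90
80,6.410
100,3.640
150,1.290
160,1.160
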