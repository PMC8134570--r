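energy_keV,mu_over_rho_cm2_g
10,0.6466
15,0.3410
20,0.2251
30,0.1792
40,0.1640
50,0.1554
60,0.1493
80,0.1401
100,0.1328
150,0.1190
160,0.1170
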