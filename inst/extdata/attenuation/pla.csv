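energy_keV,mu_over_rho_cm2_g
10,3.990
15,1.300
20,0.6650
30,0.3340
40,0.2520
50,0.2190
60,0.2010
80,0.1810
100,0.1690
150,0.1490
160,0.1460
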