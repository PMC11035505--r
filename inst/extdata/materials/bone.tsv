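# Cortical bone photon mass attenuation and mass energy-absorption
# coefficients, 15 keV - 1 MeV. Homogenized-skeleton voxels use these
# coefficients with a reduced density (label override).
# columns: energy_keV, mu_over_rho_cm2_g, mu_en_over_rho_cm2_g
15	9.032	6.323
20	4.001	2.880
30	1.331	0.9349
40	0.6655	0.4200
50	0.4242	0.2281
60	0.3148	0.1480
80	0.2229	0.07873
100	0.1855	0.05476
150	0.1480	0.03745
200	0.1309	0.03418
300	0.1113	0.03270
400	0.09908	0.03245
500	0.09022	0.03209
600	0.08332	0.03155
800	0.07308	0.03032
1000	0.06566	0.02905
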