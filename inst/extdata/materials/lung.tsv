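# Lung tissue (inflated): elemental composition is close to soft tissue, so
# the soft-tissue mass coefficients are used; the default density 0.26 g/cm3
# carries the inflation.
# columns: energy_keV, mu_over_rho_cm2_g, mu_en_over_rho_cm2_g
15	1.693	1.396
20	0.8205	0.5576
30	0.3783	0.1568
40	0.2688	0.06943
50	0.2262	0.04199
60	0.2048	0.03164
80	0.1823	0.02568
100	0.1693	0.02517
150	0.1492	0.02735
200	0.1358	0.02936
300	0.1175	0.03161
400	0.1051	0.03247
500	0.09593	0.03267
600	0.08870	0.03252
800	0.07789	0.03175
1000	0.07003	0.03073
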