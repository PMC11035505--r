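# Borosilicate glass (Pyrex-like) photon mass attenuation and mass
# energy-absorption coefficients, 15 keV - 1 MeV, approximated from a
# silica-dominated composition. Used for the reference vial wall.
# columns: energy_keV, mu_over_rho_cm2_g, mu_en_over_rho_cm2_g
15	2.941	2.577
20	1.313	1.042
30	0.4925	0.2862
40	0.3166	0.1260
50	0.2469	0.06962
60	0.2154	0.04731
80	0.1846	0.03158
100	0.1691	0.02785
150	0.1468	0.02760
200	0.1331	0.02885
300	0.1148	0.03077
400	0.1026	0.03153
500	0.09365	0.03169
600	0.08659	0.03151
800	0.07602	0.03071
1000	0.06836	0.02970
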