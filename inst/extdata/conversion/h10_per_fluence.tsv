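# Ambient dose equivalent per unit fluence h*(10), monoenergetic photons,
# transcribed from the standard operational-quantity conversion tables
# (ICRP-74). Queried by log-log interpolation, exact at nodes.
# columns: energy_keV, h10_pSv_cm2
10	0.061
15	0.83
20	1.05
30	0.81
40	0.64
50	0.55
60	0.51
80	0.53
100	0.61
150	0.89
200	1.20
300	1.80
400	2.38
500	2.93
600	3.44
800	4.38
1000	5.20
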