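# I-131 photon emission spectrum (gamma lines and Xe K X-rays), transcribed
# from a standard decay-data compilation (ICRP-107 style). Beta emissions are
# excluded: the framework scores external photon dose at >= 30 cm.
# half_life_s: 693377.3
# columns: energy_keV, intensity (photons per decay)
29.458	0.0139
29.779	0.0257
33.600	0.0059
80.185	0.0262
177.214	0.00270
272.498	0.000578
284.305	0.0612
318.088	0.000776
325.789	0.00274
364.489	0.8150
404.814	0.000547
503.004	0.00359
636.989	0.0716
642.719	0.00217
722.911	0.0177
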