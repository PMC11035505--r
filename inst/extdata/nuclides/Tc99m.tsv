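# Tc-99m photon emission spectrum, transcribed from a standard decay-data
# compilation (ICRP-107 style). Photons below 15 keV (L X-rays) are omitted:
# they are absorbed within millimetres of tissue and carry no external dose.
# half_life_s: 21624.1
# columns: energy_keV, intensity (photons per decay)
18.2508	0.0112
18.3671	0.0213
20.6190	0.0058
140.511	0.8850
142.630	0.000187
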