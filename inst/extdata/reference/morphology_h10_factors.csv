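# Benchmark per-source-region ambient dose equivalent rate factors at 1 m
# (uSv/h per MBq in the region) for a Tc-99m bone-scan patient, across four
# adult male computational models of similar height and increasing mass
# (M0A-M0D) and an adult female reference voxel phantom. Published
# multi-centre benchmark values, bundled as validation input.
# Note: the M0B kidneys entry is anomalous in the published table (order of
# magnitude off against the printed max/min ratio of 2.0, likely a typo).
source_region,M0A,M0B,M0C,M0D,ICRP_female
Urinary bladder content,1.82e-02,1.27e-02,1.34e-02,1.15e-02,2.06e-02
Kidneys,1.29e-02,8.28e-02,1.12e-02,8.13e-03,1.61e-02
Remainder,1.41e-02,1.48e-02,1.42e-02,1.37e-02,1.50e-02
Bone surface,1.31e-02,1.11e-02,1.16e-02,9.63e-03,1.09e-02
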