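# Body morphology of the computational models used in the sensitivity study
# on patient-model morphology: four adult male models of similar height and
# a body mass spanning 50-85 kg.
model,height_cm,mass_kg
M0A,162.7,50.8
M0B,164,60.2
M0C,164,71.9
M0D,165.5,85.3
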