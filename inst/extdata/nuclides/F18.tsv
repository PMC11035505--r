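# F-18 photon emission spectrum. The positron yield (0.9686 per decay) is
# folded into the two 511 keV annihilation quanta, stored as a single line
# of intensity 2 x 0.9686 (intensities above 1 denote annihilation pairs);
# positron transport itself is out of scope (photon external dose only).
# half_life_s: 6586.2
# columns: energy_keV, intensity (photons per decay)
511.0	1.9372
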