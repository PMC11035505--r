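# Water buildup coefficients for the point-kernel engine, two-argument
# Berger-type form for a far detector in air:
#   B(tau_f, tau_b) = [1 + a tau_f exp(b tau_f)]
#                   * [1 + beta exp(-gamma tau_f) (1 - exp(-1.5 D))]
# with tau_f the forward optical depth from the source voxel to the
# detector (air excluded), tau_b the backing optical depth behind the
# source (away from the detector), D = max(tau_b - tau_f, 0) the excess
# backing driving backscatter. Computed with the package's own Monte
# Carlo engine (ambient-dose-equivalent-weighted point tally at 1 m):
# a, b from a point source at the centre of a water sphere of optical
# radius tau_f; beta, gamma from a source at depth in a thick backed
# water slab. Linear interpolation in log energy between rows. An
# approximation: tissue/bone paths are treated as water-equivalent at
# the ray's total optical depth.
# columns: energy_keV, a, b, beta, gamma
20	0.100	0.164	0.166	0.612
30	0.577	-0.088	0.251	0.873
40	0.800	0.065	0.444	0.701
50	0.931	0.162	0.923	0.784
60	0.991	0.241	1.018	0.746
80	0.999	0.310	0.991	0.528
100	0.949	0.331	0.870	0.386
140	0.845	0.345	0.746	0.108
200	0.776	0.332	0.581	0.021
300	0.733	0.287	0.546	0.000
364	0.733	0.254	0.491	0.000
511	0.671	0.228	0.402	0.000
662	0.647	0.202	0.320	0.000
1000	0.647	0.156	0.293	0.000
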