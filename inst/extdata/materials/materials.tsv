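# Material index: default mass density (g/cm3) and mean ratio of atomic
# number to mass number Z/A (electrons per atomic mass unit), used to build
# the Compton component of the attenuation from the Klein-Nishina cross
# section. Densities are defaults; voxel-phantom labels may override them
# (e.g. homogenized skeleton at 1.40 g/cm3 uses the bone coefficients).
# columns: name, density_g_cm3, z_over_a
water	1.000	0.5551
soft_tissue	1.050	0.5500
bone	1.920	0.5148
lung	0.260	0.5500
air	0.001205	0.4992
glass	2.230	0.4973
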