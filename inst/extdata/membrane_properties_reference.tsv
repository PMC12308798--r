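system	analog	apl_xy	apl_xy_sd	membrane_thickness	membrane_thickness_sd	bilayer_thickness	bilayer_thickness_sd
single_bilayer	MMG-1	39.8	0.1	36.3	0.5	36.3	0.5
single_bilayer	MMG-6	42.9	0.2	30.5	1.1	30.5	1.1
double_bilayer	MMG-1	41.2	0.1	83.2	0.9	41.6	3.7
double_bilayer	MMG-6	45.7	0.1	63.7	2.4	31.9	2.3
interdigitated	MMG-1	72.0	0.1	47.7	0.1	23.9	0.7
interdigitated	MMG-6	73.2	0.1	46.1	0.5	23.1	0.7
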