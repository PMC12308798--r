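system	analog	stereoisomer	tau1_ns	a1	tau2_ns	a2
single_bilayer	MMG-1	2R3S	2.1	0.23	57.3	0.12
single_bilayer	MMG-1	2S3R	2.0	0.22	45.1	0.12
single_bilayer	MMG-6	2R3R	1.6	0.22	77.0	0.10
single_bilayer	MMG-6	2S3S	1.6	0.21	86.0	0.10
double_bilayer	MMG-1	2R3S	3.9	0.13	104.9	0.11
double_bilayer	MMG-1	2S3R	3.5	0.12	90.9	0.10
double_bilayer	MMG-6	2R3R	2.9	0.11	115.6	0.12
double_bilayer	MMG-6	2S3S	2.9	0.11	124.9	0.12
interdigitated	MMG-1	2R3S	6.6	0.13	104.4	0.13
interdigitated	MMG-1	2S3R	5.5	0.13	91.3	0.12
interdigitated	MMG-6	2R3R	3.8	0.09	132.1	0.14
interdigitated	MMG-6	2S3S	3.8	0.09	129.0	0.13
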