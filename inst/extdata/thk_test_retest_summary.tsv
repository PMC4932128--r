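roi_name	mean_abs_pct	sd_abs_pct	icc
frontal_cortex	1.2	0.91	0.98
temporal_cortex	1.83	1	0.86
parietal_cortex	1.17	1.56	0.9
occipital_cortex	1.63	1.71	0.95
insular_cortex	1.74	0.98	0.9
anterior_cingulate_gyrus	2.09	1.27	0.93
posterior_cingulate_gyrus	3.29	2.12	0.52
hippocampus	3.81	2.21	0.94
putamen	1.51	1.07	0.98
caudate_nucleus	5.27	7.96	0.97
thalamus	2.54	2.27	0.95
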