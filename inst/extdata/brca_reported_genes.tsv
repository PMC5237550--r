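gene	direction	GE_mean_gain	GE_mean_loss	GE_mean_neutral	GE_mean_diff	CNA_prop_gain	CNA_prop_loss	p_value	fdr
GNPAT	gain	0.372	-1.048	-0.200	0.601	0.558	0.015	3.01e-61	3.43e-58
SETDB1	gain	0.505	NA	-0.056	0.562	0.556	0	4.55e-58	2.60e-55
ANGEL2	gain	0.588	-0.664	0.032	0.577	0.549	0.013	1.30e-55	4.93e-53
GSTM1	loss	0.588	-0.961	0.026	-1.281	0.310	0.409	1.02e-33	5.10e-31
TOX	loss	-2.599	-3.237	-2.455	-0.777	0.023	0.337	1.64e-19	4.10e-17
LYN	loss	0.224	-0.134	0.279	-0.410	0.034	0.314	4.16e-19	6.92e-17
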