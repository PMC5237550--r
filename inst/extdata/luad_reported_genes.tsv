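gene	direction	GE_mean_gain	GE_mean_loss	GE_mean_neutral	GE_mean_diff	CNA_prop_gain	CNA_prop_loss	p_value	fdr
EIF1AX	gain	8.798	9.029	8.060	0.731	0.275	0.005	4.23e-21	1.21e-18
RAP2C	gain	7.599	NA	7.093	0.505	0.285	0.000	3.33e-12	4.78e-10
ALAS2	gain	5.765	NA	6.213	-0.448	0.347	0.000	1.64e-11	1.18e-09
RPS4Y1	loss	NA	6.507	9.472	-2.965	0.000	0.383	6.16e-28	1.54e-26
TTTY15	loss	5.988	4.463	4.955	-0.510	0.010	0.420	1.51e-17	1.88e-16
PRKY	loss	6.408	4.800	5.154	-0.363	0.005	0.358	7.81e-17	6.51e-16
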