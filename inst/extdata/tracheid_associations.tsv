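trait	marker_id	region	alleles	inclusion_frequency	pve_percent	two_a	d	d_over_a
MFA_CORE	MA_10117352g0010_1285	Synonymous	T/C	0.548	1.47	0.403	0.168	0.836
MFA_OUTER	MA_10434903g0010_8217	Intron variant	T/A	0.600	1.03	0.190	-0.002	-0.025
TWr_EW	MA_10435070g0010_17636	Missense	T/C	0.627	3.16	0.349	-0.053	-0.304
TWr_LW	MA_336364g0010_6123	Missense	C/T	0.665	0.05	0.007	-0.039	-11.489
TWr_LW	MA_11172g0010_18275	Splice variant	A/G	0.579	0.01	0.051	-0.078	-3.058
TWr_LW	MA_10433459g0010_6695	Upstream	G/T	0.604	1.72	0.118	0.042	0.701
TWr_LW	MA_64438g0010_10851	Missense	A/C	0.546	0.03	0.395	0.024	0.123
TWr_LW	MA_96801g0010_10438	Synonymous	C/T	0.547	0.10	0.212	0.022	0.211
TWr_LW	MA_950574g0010_7132	Upstream	T/A	0.558	0.05	0.451	0.004	0.017
TWr_LW	MA_7460525g0010_2105	Upstream	G/A	0.561	2.27	0.140	0.045	0.642
TWt_EW	MA_10239556g0010_	Upstream	T/G	0.633	1.80	0.072	0.002	0.069
TWt_TW	MA_10436040g0010_61320	Upstream	G/A	0.661	2.13	0.003	-0.039	-24.638
TWt_Ring	MA_10436040g0010_61320	Upstream	G/A	0.566	3.79	0.019	-0.046	-4.646
WT_EW	MA_80033g0010_7384	Missense	T/C	0.541	0.01	0.047	0.0007	0.033
WT_EW	MA_105586g0010_7132	Missense	T/C	0.536	0.10	0.032	-0.002	-0.114
WT_EW	MA_17843g0010_11398	Missense	A/G	0.546	0.01	0.021	0.010	0.976
WT_EW	MA_492000g0010_1672	Upstream	A/T	0.582	0.10	0.032	-0.021	-1.277
WT_LW	MA_5g0010_86525	Upstream	G/A	0.876	0.01	0.046	0.008	0.356
WT_LW	MA_9125g0010_34791	Upstream	T/C	0.640	0.10	0.053	0.004	0.131
WT_LW	MA_885527g0010_4213	Upstream	C/T	0.795	0.02	0.059	0.018	0.591
WT_LW	MA_9357928g0010_1204	Upstream	G/A	0.567	0.02	0.060	-0.024	-0.809
WT_LW	MA_10426383g0010_7358	Synonymous	A/G	0.610	1.57	0.097	-0.0007	-0.015
WT_Ring	MA_492000g0010_1596	Synonymous	T/C	0.726	1.78	0.038	-0.003	-0.163
WT_Ring	MA_9563494g0010_4010	Missense	G/T	0.509	0.01	0.084	-0.019	-0.464
WT_Ring	MA_138164g0010_2032	Downstream	C/T	0.529	1.25	0.007	0.001	0.442
C_EW	MA_105586g0010_7132	Missense	T/C	0.633	2.08	5.481	-0.238	-0.087
C_TW	MA_373300g0010_1844	Upstream	C/T	0.559	3.62	1.905	0.791	0.831
C_TW	MA_10426383g0010_7358	Synonymous	A/G	0.530	3.25	9.214	0.533	0.116
C_LW	MA_15229g0010_	Upstream	A/T	0.512	0.78	4.120	1.448	0.703
C_LW	MA_10426383g0010_7358	Synonymous	A/G	0.635	1.40	9.434	0.146	0.031
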