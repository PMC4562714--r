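gene_name	gene_id	candidate	cov_1	shapiro_p_1	ks_p_1	cov_2	shapiro_p_2	ks_p_2
F-box protein2	Glyma.02G273700	TRUE	0.094	0.819	0.992	0.197	0.960	0.981
RHA	Glyma.08G113000	TRUE	0.158	0.588	0.896	0.198	0.974	0.995
Bic-C1	Glyma.08G349900	TRUE	0.106	0.390	0.747	0.152	0.026	0.460
Bic-C2	Glyma.03G064800	TRUE	0.193	0.443	0.942	0.177	0.883	0.995
VPS-like	Glyma.09G196600	TRUE	0.137	0.754	0.938	0.183	0.697	0.995
SF	Glyma.05G117600	TRUE	0.181	0.140	0.663	0.137	0.081	0.760
GPX	Glyma.08G013800	TRUE	0.161	0.924	0.994	0.236	0.187	0.813
G6PD	Glyma.16G063200	FALSE	0.805	0.096	0.573	1.269	1.228E-05	0.130
ACT2/7	Glyma.19G147900	FALSE	0.294	0.507	0.848	0.776	1.588E-05	0.096
UBQ10	Glyma.07G199900	FALSE	0.652	0.087	0.389	0.856	2.837E-04	0.119
TUB4	Glyma.03G124400	FALSE	0.459	0.003	0.369	0.730	0.001	0.301
TUB4	Glyma.19G127700	FALSE	0.271	0.041	0.581	0.528	0.177	0.629
ACT11	Glyma.18G290800	FALSE	0.315	0.999	0.999	0.730	0.000	0.152
ACT11	Glyma.02G091900	FALSE	0.447	0.563	0.931	0.597	0.001	0.133
ELF-1b	Glyma.14G039100	FALSE	0.382	0.061	0.732	0.555	0.001	0.223
ELF-1b	Glyma.02G276600	FALSE	0.460	0.133	0.734	0.423	0.320	0.725
ELF-1a	Glyma.05G114900	FALSE	0.140	0.609	0.876	0.414	0.004	0.488
ELF-1a	Glyma.19G052400	FALSE	0.159	0.387	0.900	0.340	0.027	0.466
CYP	Glyma.12G024700	FALSE	0.278	0.210	0.582	0.361	0.618	0.929
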