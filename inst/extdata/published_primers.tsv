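name	forward	reverse	gene_id
Bic-C1	GTATGCTGATCGGGTGGAGA	AGCTGGGGTTCATCATCCTC	Glyma.08G349900
Bic-C2	GCCTTAATGATGTGAATGGT	AGAGATCATGTTCCCACTTG	Glyma.03G064800
F-box protein2	TGAGAAAGCTGTTGAGGATT	GATTGCTCTTAAATCCATGC	Glyma.02G273700
GPX	TCTCTATTTCAGCCACTCGT	GGTTTGAAGGAAGTGTGAAG	Glyma.08G013800
RHA	ACTGGTAGATTTGCTGGAGA	CTTATTTGTGGCTCAAAACC	Glyma.08G113000
SF	CTCTCTTCGACAAGTATGGG	CAAACTGGACCGTTATTTCG	Glyma.05G117600
VPS-like	AAAGAGTCTCATCCCACAAC	CGCATATTCCCAATCTCAGA	Glyma.09G196600
ACT11.C	ATTTTGACTGAGCGTGGTTATTCC	GCTGGTCCTGGCTGTCTCC	Glyma.18G290800;Glyma.02G091900
ACT2/7.A	CTTCCCTCAGCACCTTCCAA	GGTCCAGCTTTCACACTCCAT	Glyma.19G147900
CYP.B	ACGACGAAGACGGAGTGG	CGACGACGACAGGCTTGG	Glyma.12G024700
ELF1a	GACCTTCTTCGTTTCTCGCA	CGAACCTCTCAATCACACGC	Glyma.05G114900;Glyma.19G052400
ELF1b.B	CCACTGCTGAAGAAGATGATGATG	AAGGACAGAAGACTTGCCACTC	Glyma.02G276600;Glyma.14G039100
G6PD	ACTCCTTGATACCGTTGTCCAT	GTTTGTTATCCGCCTACAGCCT	Glyma.16G063200
TUB4.B	TGGCGTCCACATTCATTG	GAACTCCATCTCGTCCAT	Glyma.03G124400;Glyma.19G127700
UBQ10	TCCCACCAGACCAGCAGAG	CACGAAGACGCAACACAAGG	Glyma.07G199900
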