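marker	chrom	start	end	left_flank	units	copies	spacers	right_flank
SYN001	chrS	1000	1087	GTCTGCTCATAAGAGGGCTGGGCGCGGATA	TCT	29		AATGTGTTCGATGTAACCTGCTCAGCAATG
SYN002	chrS	2000	2150	ACGGACCACATGCATTGTTAGAGCAACAGG	GGAGCG	25		CCAAGTTCACGCGGTAGCGATAGACGCGTC
SYN003	chrS	3000	3168	AATGAAGGGCATTCCCTGTATCTTCGGCAA	GTAT;ACGG	16;26	ACTCGCA;	ATATATATAAGGTCGGAGGTAGAATCCTAG
SYN004	chrS	4000	4050	GCCGGCGTTAAGTTTATGTCGAGAGACCCA	TAGAG	10		CGACGCGACGAGACCATTTACGATTGAAAT
SYN005	chrS	5000	5196	TAGACCCTAGCTGACCCGTGATCAGTTCGA	ACAATC;GTGCT	21;14	AAGTC;	CATTAACCGATTGTTTCGTTTGTTTTAGTC
SYN006	chrS	6000	6120	TTCTGAGCGAAATTCACTAGCGGTGTATGA	CAGTAT	20		GCCCAAGTGCACCGAGCTGAATTTTTGGAG
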