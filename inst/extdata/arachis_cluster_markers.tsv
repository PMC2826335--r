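marker	n_alleles
04_Dal_PHYA	9
09_Lup_CycB	29
12_Lup_ACS2	28
34_Lup_app	23
63_Stylo_IGS	8
66_Stylo_SSR4-5	7
69_Stylo_IGS	4
68_Stylo_SSR1-24	10
76_Stylo_IGS	7
IPAHM117	11
IPAHM130	8
IPAHM164	15
IPAHM165	16
IPAHM273	10
IPAHM320	17
IPAHM372	18
IPAHM357	15
IPAHM377	13
IPAHM407a	17
IPAHM409	11
IPAHM171c	16
IPAHM109	8
IPAHM324	8
IPAHM105	18
IPAHM414	15
IPAHM288	20
IPAHM82	20
IPAHM606	16
IPAHM176	16
IPAHM395	13
IAPHM245	8
IAPHM406	20
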