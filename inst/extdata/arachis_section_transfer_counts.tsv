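section	n_genomic_transferable	n_genomic_total	n_genic_transferable	n_genic_total
Arachis	82	82	19	19
Caulorrhizae	56	82	17	19
Erectoides	71	82	18	19
Heteranthae	69	82	19	19
Procumbentes	69	82	19	19
Triseminatae	49	82	12	19
Extranervosae	41	82	13	19
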