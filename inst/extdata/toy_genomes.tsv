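genome_id	kingdom	phylum	genus	gc
euk_g0001	eukaryote	Chordata	eukGenus05	0.394824146288313
bac_g0001	bacterium	Firmicutes	bacGenus04	0.490629008396883
arc_g0001	archaeon	Euryarchaeota	arcGenus08	0.431510038712681
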