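taxon	guild	n_genomes
Prevotella	guild1	8
Coprococcus	guild1	7
Clostridium fessum	guild1	3
Lachnospira	guild1	3
Veillonella	guild1	3
Enterocloster	guild1	2
Faecalibacterium longum	guild1	2
Roseburia inulinivorans	guild1	2
Faecalibacterium prausnitzii	guild1	1
Fusicatenibacter saccharivorans	guild1	1
Phascolarctobacterium succinatutens	guild1	1
Haemophilus parainfluenzae	guild1	1
Lachnospira	guild2	3
Escherichia coli	guild2	2
unnamed taxa (15 distinct, one genome each)	guild2	15
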