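exon_id	exon_size	donor_exonic	donor_intronic	intron_size	acceptor_intronic	acceptor_exonic	exon_class
2	518	TTGCAG	gtaggtgtgaggcata	274879	tctcctctcttttcag	GCAACC	common
3a	45	TACCAG	gtgagttcgctgttga	43797	tctcttctggtttcag	TTGGCC	common
3b	48	GAACAG	gtgcgtacttccttaa	85670	tcgtttccaatttcag	ACGACG	common
4	135	ACGAAG	gtatgggggttcttac	13860	cttctctgcctcgcag	GTCAAG	common
5a	461	gttgag	gtcattataagcttcc	208	acataatgaccacagt	GCAAAT	female_specific
5b	465	cgacag	gtactgctattggagg	10392	tcaatccctcaaacag	GATACG	female_specific
6	1063	acgaag	gtgagtgttctttttt	22437	ctcttttcttcaacag	tttcac	common
7	449	NA	NA	NA	NA	NA	common
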