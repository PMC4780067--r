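coordinates	gene	protein	allele_frequency	mutation_expressed	ref_allele_expressed
chr22: 24145582C>T	SMARCB1	NP_003064.2:p.Arg201*	87.5	Yes	Yes
chr8: 145739905G>A	RECQL4	NP_004251.3:p.Ser542Phe	55.3	No	Yes
chr1: 27100206insGCA	ARID1A	NP_006006.3:p.Gln1334insGln	28.2	No	Yes
chr1: 40366547C>G	MYCL1	NP_005367.2:p.Cys217Ser	55	No	No
chrX: 53227814C>G	KDM5C	NP_004178.2:p.Glu792Gln	100	Yes	No
chr11: 71727189G>A	NUMA1	NP_006176.2:p.Arg454Trp	80	Yes	Yes
chr8: 17815114G>A	PCM1	NP_006188.3:p.Glu624Lys	45.5	Yes	Yes
chr3: 1269653C>T	CNTN6	NP_055276.1:p.Arg112Trp	80	No	No
chr20: 44520260delTG	CTSA	NP_000299.2:p.Leu36fs	26.7	No	Yes
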