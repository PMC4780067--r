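coordinates	gene	protein	allele_frequency	mutation_expressed	ref_allele_expressed
chr22: 42390734delG	SEPT03	NP_061979.3:p.Glu343fs	13.8	no	Yes (35)
chrX: 103294635C>T	H2BFM	NP_001157888.1:p.Thr31Met	6.7	no	No (0)
chr3: 147113718insA	ZIC4	NP_115529.2:p.Phe204fs	7.4	no	Yes (55)
chr1: 149859313G>T	HIST2H2AB	NP_778235.1:p.Leu52Met	9	no	No (0)
chr19: 58102066A>T	ZIK1	NP_001010879.2:p.Glu296Val	14.6	no	Yes (11)
chr21: 31965069A>C	KRTAP6-3	NP_853636.3:p.Tyr102Ser	17	no	No (0)
chr9: 21409401G>A	IFNA8	NP_002161.2:p.Ala76Thr	5.7	no	No (0)
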