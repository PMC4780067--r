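CHROMATIN_REMODELLING	synthetic example set	SMARCB1	ARID1A	KDM5C	SMARCA4	PBRM1
MITOTIC_SPINDLE	synthetic example set	NUMA1	PCM1	ASPM	KIF11	TPX2	AURKA
INTERFERON_ALPHA	synthetic example set	IFNA8	IFNA2	IFNAR1	STAT1	STAT2
KERATINIZATION	synthetic example set	KRTAP6-3	KRT14	KRT5	IVL
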