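Spectrum	Peptide	Charge	Assigned Modifications	Total Glycan Composition
sample01.7.7.3	PEPTIDEK	3		HexNAc2-Hex5
sample01.9.9.2	NGSLK	2		HexNAc1
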