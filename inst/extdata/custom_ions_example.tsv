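name	mz	composition	adducts
HexNAzoSi	345.14		
HexNAc+formyl		HexNAc:1	CO
NeuAc+formyl		NeuAc:1	CO
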