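glycan	mass
HexNAc2-Hex5	1216.42286
HexNAc2-Hex5-dHex1	1362.48077
HexNAc1	203.07937
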