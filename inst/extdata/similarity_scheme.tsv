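# default functional-similarity scheme: class <TAB> residues
beta_branched	IV
aliphatic	LIVAM
aromatic	FYW
basic	KRH
acidic	DE
amide	NQ
small	GAS
thiol	CU
proline	P
threonine	T
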