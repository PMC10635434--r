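id	iupac	max_mismatches
TCS	CATTCY	0
MIG1	SYGGGG	0
MAL63	CGGNNNNNNNNCGG	0
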