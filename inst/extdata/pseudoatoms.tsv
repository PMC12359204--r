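pseudo	codes	atoms
HN	*	H
QA	GLY	HA2,HA3
MB	ALA	CB
QB	ALA,DHA	CB
MG	ABU	CG
QG	ABU,DHB	CG
MG2	THR	CG2
QG2	THR	CG2
QB2	*	CB
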