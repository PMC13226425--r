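# Published Cbeta/Cgamma chemical shifts of the four prolines of the
# titin I82 construct (construct numbering, first residue = G1).
residue_number	residue_name	atom_name	ppm
4	PRO	CB	31.8
4	PRO	CG	26.5
9	PRO	CB	31.9
9	PRO	CG	27.4
35	PRO	CB	32.1
35	PRO	CG	26.8
50	PRO	CB	31.2
50	PRO	CG	27.8
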