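# Published backbone phi/psi torsion angles (degrees) of the EF-loop
# residues of titin I82 in the two conformers (IN/OUT), together with the
# chemical-shift-predicted values (pre) that average over the exchange.
resno	phi_in	psi_in	phi_out	psi_out	phi_pre	psi_pre
73	-83	-18	-81	-21	-63	-44
74	-78	4	-99	20	-70	-35
75	-84	-178	-110	166	-85	-7
76	121	84	132	-70	94	-41
77	-9	109	-163	137	-69	138
78	-83	138	-118	139	-119	126
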