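# Published conformer-specific NOE distance restraints for the EF-loop
# region of titin I82 (construct numbering).  upper_A is the calibrated
# upper bound; distance_IN / distance_OUT are the published effective
# distances in the best structure of each conformer.  tag marks the
# conformer whose restraint set the row belongs to.
res1	atom1	res2	atom2	upper_A	tag	distance_IN	distance_OUT
74	HB1	78	HH	2.0	OUT	2.9	2.3
75	HB1	72	HA	2.5	OUT	3.7	2.7
76	HA2	90	HG1	3.0	OUT	5.1	3.3
76	HA2	90	HG2	4.5	OUT	6.2	4.6
76	HN	92	HA	3.5	OUT	5.2	3.6
43	HD2	74	HA	2.0	OUT	3.2	2.1
74	HB3	67	HG2#	3.5	IN	3.6	4.1
75	HA	91	HG	2.5	IN	2.7	3.5
43	HG1	76	HA3	2.5	IN	2.6	5.8
43	HG2	76	HA3	2.0	IN	2.3	5.3
43	HD2	76	HA3	3.0	IN	3.3	6.1
43	HD1	76	HA3	4.0	IN	4.3	7.1
43	HA	76	HA2	4.0	IN	4.1	6.6
44	HD21	76	HA2	2.0	IN	2.3	3.6
44	HD21	76	HA3	3.5	IN	3.7	5.1
44	HN	76	HA2	4.0	IN	4.1	7.0
44	HN	76	HA3	3.5	IN	3.6	5.6
77	HE21	89	HA	3.5	IN	3.6	7.6
76	HA3	78	HE#	4.0	IN	4.3	7.3
74	HB3	70	HG1#	4.0	IN	4.1	6.3
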