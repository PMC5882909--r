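id_a	id_b	ka	ks	ratio_printed	date_printed	selection_printed	dup_type_printed
GaCAMTA2.1	GaCAMTA2.2	0.1019	0.3907	0.2607	13.02	Purifying selection	Segmental
GaCAMTA5.1	GaCAMTA5.2	0.1456	0.4511	0.3228	15.03	Purifying selection	Segmental
GrCAMTA2.2	GrCAMTA2.1	0.1018	0.4104	0.248	13.68	Purifying selection	Segmental
GrCAMTA5.1	GrCAMTA5.2	0.1233	0.3625	0.3401	12.08	Purifying selection	Segmental
GrCAMTA5.1	GrCAMTA5.3	0.1472	0.403	0.3653	13.43	Purifying selection	Segmental
GhCAMTA2A.1	GhCAMTA2A.2	0.0996	0.3914	0.2545	13.04	Purifying selection	Segmental
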