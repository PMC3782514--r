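pair	overlap_bp	conserved_bp	csr_printed	cfs_printed
A T.urartu : A T.durum	123270	82563	67.0	9173
A T.urartu : A T.aestivum	99054	71138	71.8	10162
A T.urartu : B T.durum	25902	12173	46.9	1739
A T.durum : A T.aestivum	96932	95924	98.9	47962
B T.durum : B T.aestivum	68851	68767	99.9	34383
B T.durum : D Ae.tauschii	63512	13569	21.4	3392
D Ae.tauschii : D T.aestivum	81518	76344	93.7	19086
A T.aestivum : B T.aestivum	32422	12911	39.8	2582
A T.urartu : D Ae.tauschii	63619	14427	22.7	3606
A T.aestivum : D T.aestivum	58405	16530	28.3	2066
B T.aestivum : D T.aestivum	58321	14105	24.2	3526
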