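element_pair	genome	K	time_printed_mya
RLG_Sabrina_105A8-1 : RLG_Sabrina_1051O6-1	A	0.0178	0.68
RLG_Sabrina_105A8-1 : RLG_Sabrina_351D1-1	A	0.0177	0.68
RLG_Sabrina_1051O6-1 : RLG_Sabrina_351D1-1	A	0.0001	0.00
RLC_WIS_1051O6-1 : RLC_WIS_351D1-1	A	0.0008	0.03
RLC_WIS_1051O6-2 : RLC_WIS_351D1-2	A	0.0002	0.01
RLG_Fatima_315P18-1 : RLG_Fatima_17O6-1	B	0.0003	0.01
RLG_Fatima_315P18-2 : RLG_Fatima_17O6-2	B	0.0009	0.03
RLC_WIS_C4-3 : RLC_WIS_1J9-7	D	0.0038	0.15
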