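pair	gene1_coding_K	gene1_intron_K	gene1_time_printed	gene2_Ks	gene2_time_printed	avg_time_printed	is_calibration
A T.urartu : A T.durum	0.0068	0.0094	0.2893	0.0329	2.2671	1.2782	0
A T.urartu : A T.aestivum	0.0068	0.0094	0.2893	0.0329	2.2671	1.2782	0
A T.urartu : B T.durum	0.0585	0.0094	1.2124	0.3227	22.2373	11.7248	0
A T.urartu : D Ae.tauschii	0.0666	0.0613	2.2837	0.2003	13.8027	8.0432	0
A T.durum : A T.aestivum	0.0000	0.0000	0.0000	0.0000	0.0000	0.0000	0
B T.durum : B T.aestivum	0.0000	0.0000	0.0000	0.0080	0.5513	0.2756	0
B T.durum : D Ae.tauschii	0.0418	0.0996	2.5248	0.2558	17.6272	10.0760	0
D Ae.tauschii : D T.aestivum	0.0031	0.0000	0.0554	0.0000	0.0000	0.0277	0
A T.aestivum : B T.aestivum	0.0658	0.1245	3.3979	0.2949	20.3216	11.8597	0
A T.aestivum : D T.aestivum	0.0705	0.0611	2.3498	0.2409	16.6004	9.4751	0
B T.aestivum : D T.aestivum	0.0384	0.0996	2.4641	0.2487	17.1379	9.8010	0
D T.aestivum : B.distachyon	0.2832	0.7398	18.2662	0.8594	59.2213	38.7438	0
D T.aestivum : S.bicolor	0.5683	1.8217	42.6748	0.9806	67.5732	55.1240	0
D T.aestivum : S.italica	0.6111	1.3976	35.8664	0.8741	60.2343	48.0504	0
D T.aestivum : O.sativa	0.4948	2.9005	60.6249	1.0089	69.5234	65.0742	0
D T.aestivum : Z.mays	0.6321	1.6672	41.0553	1.2046	83.0091	62.0322	0
O.sativa : S.bicolor	0.5414	2.8189	60.0000	0.8707	60.0000	60.0000	1
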