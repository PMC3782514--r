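pair	utr5_len	utr5_K	cds_len	Ks	Ka	KaKs_printed	utr3_len	utr3_K
A T.urartu : A T.durum	627	0.0067	1860	0.0329	0.0000	0.0010	805	0.0029
A T.urartu : A T.aestivum	627	0.0067	1860	0.0329	0.0000	0.0010	805	0.0029
A T.urartu : B T.durum	627	0.1210	1875	0.3227	0.0045	0.0140	822	0.0886
A T.urartu : D Ae.tauschii	630	0.0482	1876	0.2003	0.0146	0.0729	814	0.0629
A T.durum : A T.aestivum	623	0.0000	1860	0.0000	0.0000	0.0010	791	0.0000
B T.durum : B T.aestivum	579	0.0000	1863	0.0080	0.0000	0.0010	795	0.0000
B T.durum : D Ae.tauschii	629	0.1239	1881	0.2558	0.0159	0.0622	827	0.0600
D Ae.tauschii : D T.aestivum	607	0.0034	1869	0.0000	0.0000	0.0010	784	0.0059
A T.aestivum : B T.aestivum	639	0.1321	1872	0.2949	0.0045	0.0153	837	0.0925
A T.aestivum : D T.aestivum	636	0.0513	1872	0.2409	0.0145	0.0602	806	0.0670
B T.aestivum : D T.aestivum	637	0.1288	1878	0.2487	0.0159	0.0639	830	0.0605
D T.aestivum : B.distachyon	639	0.4931	1899	0.8594	0.0404	0.0470	796	0.4439
D T.aestivum : S.bicolor	631	0.5740	1917	0.9806	0.0677	0.0690	845	0.6488
D T.aestivum : S.italica	655	1.1462	1908	0.8741	0.0551	0.0630	869	0.5472
D T.aestivum : O.sativa	655	0.7067	1896	1.0089	0.0614	0.0609	799	0.6211
D T.aestivum : Z.mays	623	0.5713	1917	1.2046	0.0584	0.0485	802	0.6925
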