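dataset	predictor	msa	L5	L10	L20	L50	top50	top20	top10	top5
heterodimer100	trRosettaX	genomic	0.273	0.325	0.372	0.414	0.302	0.365	0.397	0.424
heterodimer100	trRosettaX	phylogeny	0.353	0.430	0.499	0.564	0.394	0.485	0.538	0.577
heterodimer100	trRosettaX	string	0.210	0.253	0.295	0.333	0.228	0.282	0.316	0.338
heterodimer100	trRosettaX	cascade	0.398	0.491	0.572	0.645	0.449	0.560	0.629	0.673
baker	CCMpred	rf_msa	0.012	0.007	0.006	0.009	0.010	0.006	0.004	0.007
baker	CCMpred	cascade	0.137	0.214	0.306	0.377	0.242	0.333	0.385	0.400
baker	trRosettaX	rf_msa	0.340	0.416	0.462	0.535	0.406	0.461	0.519	0.556
baker	trRosettaX	cascade	0.334	0.418	0.487	0.565	0.410	0.494	0.552	0.578
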