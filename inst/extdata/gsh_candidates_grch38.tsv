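chrom	start	end	width	active_start	active_end	housekeeping_gene	blat_ratio	shortlisted
1	113289036	113289342	307	113000001	114000000	HIPK1	0.21	FALSE
1	113314841	113318369	3529	113000001	114000000	HIPK1	0.18	FALSE
1	113339961	113340514	554	113000001	114000000	HIPK1	0.27	TRUE
2	128912721	128914814	2094	128000001	129000000	UGGT1	0.08	TRUE
2	128918961	128919839	879	128000001	129000000	UGGT1	0.16	FALSE
2	128932307	128935799	3493	128000001	129000000	UGGT1	0.15	TRUE
2	128963272	128965759	2488	128000001	129000000	UGGT1	0.44	FALSE
2	208992998	208997459	4462	208000001	209000000	PIKFYVE	0.28	FALSE
4	17373361	17374159	799	17000001	18000000	MED28	0.04	TRUE
5	131058585	131058947	363	131000001	132000000	FNIP1	0.41	FALSE
5	148753741	148757219	3479	148000001	149000000	FBXO38	0.10	FALSE
6	15727241	15727490	250	15000001	16000000	DTNBP1	0.47	TRUE
7	4314741	4315279	539	4000001	5000000	FOXK1	0.15	FALSE
7	4321017	4323839	2823	4000001	5000000	FOXK1	0.09	FALSE
7	4328040	4329659	1620	4000001	5000000	FOXK1	0.21	FALSE
7	4353504	4354219	716	4000001	5000000	FOXK1	0.32	FALSE
7	4454808	4456201	1394	4000001	5000000	FOXK1	0.17	FALSE
8	23945241	23945819	579	23000001	24000000	R3HCC1	0.34	FALSE
8	23986981	23988319	1339	23000001	24000000	R3HCC1	0.06	FALSE
8	23999628	24001194	1567	23000001	24000000	R3HCC1	0.02	FALSE
18	56339813	56340245	433	56000001	57000000	TXNL1	0.06	FALSE
18	56396821	56397319	499	56000001	57000000	TXNL1	0.07	FALSE
18	56410681	56411039	359	56000001	57000000	TXNL1	0.14	FALSE
18	56534775	56536439	1665	56000001	57000000	TXNL1	0.16	TRUE
19	5400761	5402139	1379	5000001	6000000	SAFB	0.18	TRUE
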