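peak	rt_min	family	name	aglycone	residues	formula	ref_mass	ref_mz	ref_ms2
1	4.60	anthocyanidin	Peonidin Glc I	Peonidin	Glc	C22H23O11+	463.1240	463.1240	301.0702
2	4.61	flavone	Tricin GlcGlcA I	Tricin	Glc;GlcA	C29H32O18	668.1589	669.1662	507.1119;331.0817
3	5.07	isoflavone	Afrormosin Glc I	Afrormosin	Glc	C23H24O10	460.1369	461.1442	461.1418;299.0905
4	5.13	flavone	Tricin GlcGlcA II	Tricin	Glc;GlcA	C29H32O18	668.1584	669.1657	507.1119;331.0817
5	5.18	flavone	Apigenin GlcAGlcA	Apigenin	GlcA;GlcA	C27H26O17	622.1170	623.1243	271.0592
6	5.39	flavone	Chrysoeriol GlcAGlcA	Chrysoeriol	GlcA;GlcA	C28H28O18	652.1280	653.1353	477.1025;301.0709
7	5.49	flavone	Tricin GlcAGlcA	Tricin	GlcA;GlcA	C29H30O19	682.1387	683.1460	507.1119;331.0817
8	5.77	flavone	Tricin GlcGlcA III	Tricin	Glc;GlcA	C29H32O18	668.1590	669.1663	507.1119;331.0817
9	5.81	flavone	Apigenin FerGlcAGlcAGlcA I	Apigenin	Fer;GlcA;GlcA;GlcA	C43H42O26	974.1975	975.2048	799.1716;447.0922;323.0769;271.0598
10	5.90	flavone	Apigenin CouGlcAGlcAGlcA I	Apigenin	Cou;GlcA;GlcA;GlcA	C42H40O25	944.1865	945.1938	769.1589;447.0922;323.0769;271.0598
11	5.93	isoflavone	Formononetin Glc I	Formononetin	Glc	C22H22O9	430.1264	431.1337	269.0798
12	5.96	anthocyanidin	Peonidin Glc II	Peonidin	Glc	C22H23O11+	463.1240	463.1240	301.0702
13	5.97	flavone	Chrysoeriol FerGlcAGlcAGlcA	Chrysoeriol	Fer;GlcA;GlcA;GlcA	C44H44O27	1004.2073	1005.2146	477.1025;301.0709
14	6.03	flavone	Tricin Glc I	Tricin	Glc	C23H24O12	492.1268	493.1341	331.0817
15	6.08	flavone	Apigenin FerGlcAGlcAGlcA II	Apigenin	Fer;GlcA;GlcA;GlcA	C43H42O26	974.1970	975.2043	799.1716;447.0922;323.0769;271.0598
16	6.19	flavone	Apigenin GlcA	Apigenin	GlcA	C21H18O11	446.0849	447.0922	271.0587
17	6.29	isoflavone	Biochanin A MalGlc I	Biochanin A	Mal;Glc	C25H24O13	532.1217	533.1290	285.0762
18	6.30	flavone	Apigenin CouGlcAGlcAGlcA II	Apigenin	Cou;GlcA;GlcA;GlcA	C42H40O25	944.1865	945.1938	769.1589;447.0922;323.0769;271.0598
19	6.32	flavone	Apigenin FerGlcAGlcA I	Apigenin	Fer;GlcA;GlcA	C37H34O20	798.1643	799.1716	447.0926;271.0601;353.0876
20	6.36	flavone	Apigenin CouGlcAGlcA I	Apigenin	Cou;GlcA;GlcA	C36H32O19	768.1538	769.1611	447.0922;323.0769;271.0598
21	6.40	anthocyanidin	Peonidin Glc III	Peonidin	Glc	C22H23O11+	463.1240	463.1240	301.0702
22	6.40	flavone	Apigenin FerGlcAGlcAGlcA III	Apigenin	Fer;GlcA;GlcA;GlcA	C43H42O26	974.1965	975.2038	799.1716;447.0922;323.0769;271.0598
23	6.41	flavone	Chrysoeriol GlcA	Chrysoeriol	GlcA	C22H20O12	476.0955	477.1028	477.1025;353.0553;301.0709
24	6.48	flavone	Tricin Glc II	Tricin	Glc	C23H24O12	492.1268	493.1341	331.0817
25	6.53	flavone	Tricin FerGlcAGlcA I	Tricin	Fer;GlcA;GlcA	C39H38O22	858.1855	859.1928	507.1119;331.0817
26	6.58	flavone	Apigenin FerGlcAGlcA II	Apigenin	Fer;GlcA;GlcA	C37H34O20	798.1643	799.1716	447.0920;271.0607;353.0876
27	6.61	flavone	Tricin CouGlcAGlcA I	Tricin	Cou;GlcA;GlcA	C38H36O21	828.1727	829.1800	507.1119;331.0817
28	6.72	flavone	Tricin Glc III	Tricin	Glc	C23H24O12	492.1268	493.1341	331.0817
29	6.83	isoflavone	Formononetin Glc II	Formononetin	Glc	C22H22O9	430.1264	431.1337	269.0798
30	6.92	flavone	Apigenin CouGlcAGlcA II	Apigenin	Cou;GlcA;GlcA	C36H32O19	768.1538	769.1611	447.0922;323.0769;271.0598
31	6.94	isoflavone	Daidzein	Daidzein		C15H10O4	254.0579	255.0652	255.0649
32	6.95	isoflavone	Biochanin A MalGlc II	Biochanin A	Mal;Glc	C25H24O13	532.1217	533.1290	285.0762
33	6.97	isoflavone	Afrormosin Glc II	Afrormosin	Glc	C23H24O10	460.1369	461.1442	461.1418;299.0905
34	7.06	flavone	Tricin CouGlcAGlcA II	Tricin	Cou;GlcA;GlcA	C38H36O21	828.1727	829.1800	507.1119;331.0817
35	7.19	flavone	Tricin FerGlcAGlcA III	Tricin	Fer;GlcA;GlcA	C39H38O22	858.1855	859.1928	507.1119;331.0817
36	7.29	flavanone	Naringenin Chalcone Glc	Naringenin Chalcone	Glc	C21H22O10	434.1213	435.1286	391.1364;271.0432
37	7.60	pterocarpan	Medicarpin MalGlc I	Medicarpin	Mal;Glc	C25H26O12	518.1424	519.1497	271.0964
38	7.67	isoflavone	Formononetin MalGlc	Formononetin	Mal;Glc	C25H24O12	516.1268	517.1341	269.0798
39	7.71	isoflavone	Afrormosin MalGlc	Afrormosin	Mal;Glc	C26H26O13	546.1373	547.1446	547.1444;299.0907
40	8.07	flavone	Tricin Glc IV	Tricin	Glc	C23H24O12	492.1268	493.1341	331.0817
41	8.15	pterocarpan	Medicarpin MalGlc II	Medicarpin	Mal;Glc	C25H26O12	518.1424	519.1497	271.0964
42	8.24	isoflavone	Biochanin A	Biochanin A		C16H12O5	284.0684	285.0757	285.0757
43	8.39	isoflavone	Irisolidone isomer	Irisolidone		C17H14O6	314.0790	315.0863	315.0863
44	8.56	isoflavone	Formononetin	Formononetin		C16H12O4	268.0735	269.0808	269.0806
45	8.64	isoflavone	Afrormosin	Afrormosin		C17H12O5	298.0841	299.0914	299.0902
46	9.11	isoflavone	Irisolidone	Irisolidone		C17H14O6	314.0790	315.0863	315.0863
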