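miRNA	UV_ctrl	UV_stress	heat_ctrl	heat_stress	hypoxia_ctrl	hypoxia_stress	hypoxia_hif1_ctrl	hypoxia_hif1_stress
mir-sim-001	23296,191	24654,673	50635,099	90457,347	26690,747	57722,231	21271,502	95169,809
mir-sim-002	346,609	581,680	764,285	1131,042	412,411	344,951	317,594	724,893
mir-sim-003	64389,128	149643,409	153536,754	207664,563	80183,100	62025,989	63779,195	111236,018
mir-sim-004	1892,664	3322,226	4282,304	6353,546	2281,484	1827,104	1751,971	4021,091
mir-sim-005	46807,187	119120,849	104064,839	152607,340	55981,539	47032,277	44057,833	99884,965
mir-sim-006	660,433	1595,815	1444,088	2113,307	800,434	1069,491	625,052	1602,241
mir-sim-007	11895,835	32952,868	27024,643	20456,653	13843,254	7848,695	10514,503	35895,484
mir-sim-008	6696,984	9330,430	14520,765	18368,501	7819,990	10812,097	6273,982	23501,009
mir-sim-009	22142,437	37341,292	49192,886	74471,769	25602,589	22022,737	20261,033	45925,276
mir-sim-010	861,232	994,494	1895,937	5664,422	1035,623	1116,643	813,543	1096,163
mir-sim-011	189746,613	325066,307	411388,104	620235,198	219553,587	184019,234	175420,408	411153,999
mir-sim-012	4640,670	6124,715	10774,379	16024,102	5837,051	11294,750	4373,602	15739,442
mir-sim-013	5299,207	8702,062	11698,649	17255,985	6144,658	5049,046	4711,238	11322,913
mir-sim-014	47580,737	83295,734	106157,972	158842,071	57814,754	47313,786	45136,411	98644,866
mir-sim-015	90745,198	223209,968	201060,164	229162,334	105995,370	33734,675	82827,028	211516,414
mir-sim-016	46659,235	97364,395	100225,891	168573,714	54325,102	40054,064	43440,041	118793,639
mir-sim-017	18371,729	22728,581	41692,635	110392,752	21617,076	12225,061	17080,291	19127,484
mir-sim-018	468,499	856,677	1064,965	1209,840	595,994	676,696	450,464	662,435
mir-sim-019	2763,154	4756,359	6137,956	12213,732	3218,431	2877,563	2640,478	5893,868
mir-sim-020	5914,295	9545,898	13131,464	23440,144	7167,077	6413,259	5589,486	10817,934
mir-sim-021	27619,034	45025,121	58444,046	86299,339	31954,612	26751,493	24944,573	55565,827
mir-sim-022	924,304	1968,058	1984,413	2727,162	1072,003	947,570	852,195	2525,853
mir-sim-023	117466,947	205495,667	259339,160	391349,159	143316,144	114268,157	107675,162	254324,874
mir-sim-024	1524,509	2603,677	3339,743	5177,599	1849,332	1552,502	1415,644	3315,222
mir-sim-025	39237,395	84692,503	89434,317	222374,782	47712,442	55897,991	35620,455	96923,717
mir-sim-026	39582,713	87002,491	84685,369	236964,407	48059,322	44554,190	37169,191	132998,293
mir-sim-027	97585,149	123486,061	218864,634	354303,259	115823,189	120281,053	86552,007	246154,199
mir-sim-028	79436,919	239120,435	171522,048	279490,593	93445,046	45635,907	75481,055	231496,763
mir-sim-029	425,058	870,741	976,116	1071,780	535,742	516,984	390,651	1791,589
mir-sim-030	51293,443	167654,063	106342,608	174484,567	60546,597	25101,776	47510,811	190197,158
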