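id,name,formula,adduct,rt_min,class,detected_mz,calculated_mz
1,Maleic acid,C4H4O4,[M-H]-,0.796,Org,115.0045,115.0037
2,Nicotinic acid,C6H5NO2,[M+H]+,0.896,Org,124.0396,124.0393
3,Adenosine,C10H13N5O4,[M+H]+,1.006,Alk,268.1047,268.1040
4,Codonopsinol A,C13H19NO5,[M+H]+,1.053,Alk,270.1343,270.1336
5,3'-hydroxy codonopyrrolidium B,C14H22NO5+,[M]+,1.088,Alk,284.1503,284.1492
6,Succinic acid,C4H6O4,[M-H]-,1.096,Org,117.0196,117.0193
7,Codonopiloside A,C19H29NO9,[M+H]+,1.885,Alk,416.1917,416.1915
8,5-Hydroxymethyl-2-furaldehyde,C6H6O3,[M+H]+,1.992,Ter,127.0388,127.0390
9,Codonopsinol B,C13H19NO4,[M+H]+,2.068,Alk,254.1393,254.1387
10,Codonopyrrolidium B,C14H22NO4+,[M]+,2.234,Alk,268.1551,268.1543
11,Woodorien,C14H18O9,[M-H]-,2.327,Oth,329.0882,329.0878
12,Codonopsine,C14H21NO4,[M+H]+,2.550,Alk,268.1547,268.1543
13,4-Hydroxybenzoic acid,C7H6O3,[M-H]-,2.560,Org,137.0244,137.0244
14,Tryptophan,C11H12N2O2,[M+H]+,3.399,Oth,205.0977,205.0972
15,Protocatechuic acid,C7H6O4,[M-H]-,4.374,Org,153.0194,153.0193
16,Coniferoside,C16H22O8,[M+Na]+,4.531,Lig,365.1205,365.1207
17,Chlorogenic acid,C16H18O9,[M+H]+,5.265,Org,355.1028,355.1024
18,Syringin,C17H24O9,[M+Na]+,5.380,Lig,395.1306,395.1313
19,Caffeic acid,C9H8O4,[M-H]-,6.022,Org,179.0351,179.0350
20,(E)-Isoconiferin,C16H22O8,[M+Na]+,7.024,Lig,365.1204,365.1207
21,Tangshenoside II,C17H24O9,[M+COOH]-,7.503,Lig,417.1410,417.1402
22,Codonopyrrolidium I,C19H28NO6+,[M]+,7.709,Alk,366.1920,366.1911
23,Vanillin,C8H8O3,[M+H]+,7.759,Oth,153.0546,153.0546
24,3'-hydroxy codonopyrrolidium F,C19H30NO6+,[M]+,8.591,Alk,368.2067,368.2068
25,3-O-caffeoylquinic acid methyl ester,C17H20O9,[M+H]+,8.675,Org,369.1175,369.1180
26,3'-hydroxy codonopyrrolidium G,C19H30NO6+,[M]+,8.991,Alk,368.2078,368.2068
27,p-coumaric acid glucoside,C15H18O8,[M-H]-,8.934,Oth,325.0924,325.0929
28,Syringaldehyde,C9H10O4,[M+H]+,9.085,Oth,183.0653,183.0652
29,Hexyl-beta-D-glucopyranosyl-(1->2)-beta-D-glucopyranoside,C18H34O11,[M+COOH]-,10.053,Oth,471.2080,471.2083
30,Ferulic acid,C10H10O4,[M+H]+,10.322,Org,195.0649,195.0652
31,3'-hydroxy codonopyrrolidium D,C19H30NO6+,[M]+,10.389,Alk,368.2078,368.2068
32,Tangshenoside I,C29H42O18,[M-H]-,10.532,Lig,677.2310,677.2298
33,Codonopyrrolidium H,C19H30NO6+,[M]+,10.655,Alk,368.2077,368.2068
34,Hexyl-beta-D-glucopyranosyl-(1->6)-beta-D-glucopyranoside,C18H34O11,[M+COOH]-,10.796,Oth,471.2079,471.2083
35,Codonopyrrolidium A,C19H28NO5+,[M]+,11.071,Alk,350.1971,350.1962
36,Codonopyrrolidium F,C19H30NO5+,[M]+,12.103,Alk,352.2129,352.2118
37,Codonopyrrolidium G,C19H30NO5+,[M]+,12.452,Alk,352.2128,352.2118
38,Codonopyrrolidium C,C19H28NO5+,[M]+,12.918,Alk,350.1970,350.1962
39,Lobetyolinin,C26H38O13,[M+Na]+,13.401,Pol,581.2203,581.2205
40,Codonopyrrolidium D,C19H30NO5+,[M]+,13.850,Alk,352.2129,352.2118
41,Codonopyrrolidium E,C19H30NO5+,[M]+,14.216,Alk,352.2128,352.2118
42,Azelaic acid,C9H16O4,[M-H]-,14.243,Org,187.0980,187.0976
43,Lobetyolin,C20H28O8,[M+Na]+,15.888,Pol,419.1665,419.1676
44,Eucommioside II,C15H26O9,[2M-H]-,16.989,Oth,699.3069,699.3081
45,Codonoside B,C38H48O20,[M-H]-,17.089,Lig,823.2642,823.2666
46,Codonoside A,C38H48O20,[M-H]-,17.638,Lig,823.2642,823.2666
47,Lobetyol,C14H18O3,[M+Na]+,17.894,Pol,257.1142,257.1148
48,"9,10,13-Trihydroxy-(E)-11-octadecenoic acid",C18H34O5,[M-H]-,20.400,Org,329.2348,329.2333
49,"5,6,9-Trihydroxy-octadec-7-enoic acid",C18H34O5,[M-H]-,21.249,Org,329.2339,329.2333
50,Atractylenolide III,C15H20O3,[M+H]+,23.130,Ter,249.1483,249.1485
51,Octadecenoic acid,C18H34O4,[M-H]-,24.112,Org,313.2402,313.2384
52,"9,10-Dyhydroxy-12-octadecenoic acid",C18H34O4,[M-H]-,24.345,Org,313.2399,313.2384
53,Atractylenolide II,C15H20O2,[M+H]+,25.400,Ter,233.1539,233.1536
54,"9-Hydroxy-10,12-octadecadienoic acid",C18H32O3,[M-H]-,26.723,Org,295.2274,295.2279
55,Atractylenolide I,C15H18O2,[M+H]+,27.031,Ter,231.1376,231.1380
56,Linoleic acid,C18H32O2,[M-H]-,32.815,Org,279.2331,279.2330
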