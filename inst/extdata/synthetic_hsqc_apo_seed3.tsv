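# residue dH_ppm dN_ppm
1	7.7984	112.0285
2	8.9641	113.7747
3	8.1989	113.2866
4	8.1001	110.3896
5	8.5899	122.2528
6	8.5900	124.4060
7	7.7054	122.4255
8	8.0235	110.9370
9	8.5445	123.0638
10	8.6311	120.6002
11	8.4188	114.0898
12	8.4049	107.0661
13	8.4775	115.5674
14	8.4958	107.8383
15	9.0577	113.4834
16	8.9936	113.7560
17	7.7028	107.9233
18	8.7685	109.5808
19	9.1150	109.6946
20	7.9886	127.8912
21	7.9144	122.8713
22	7.5328	125.7838
23	7.7273	122.0462
24	7.6748	111.2091
25	7.9188	117.1236
26	8.9279	123.2887
27	8.5729	125.6843
28	9.1210	125.7309
29	8.5203	110.7710
30	8.8672	120.5495
31	8.1839	116.3008
32	8.1868	121.2958
34	8.3172	127.1464
35	7.9411	113.6370
36	8.1197	113.5524
37	9.0925	117.8658
38	7.8504	114.0197
39	8.5338	111.3112
40	7.8621	125.9130
41	7.9868	118.8738
42	8.9054	108.3225
43	7.8099	108.6522
44	8.5365	119.7562
45	8.2588	118.8979
46	7.9693	117.7643
47	7.5796	113.6767
48	7.7056	122.3785
49	8.0694	126.7295
50	8.9282	126.3644
51	7.9391	112.3989
52	7.8883	120.5529
53	9.0873	125.9668
54	9.2987	120.3267
55	9.0219	110.7454
56	9.1395	124.6119
57	8.3384	109.0101
58	7.8908	127.2779
59	7.7547	113.5184
60	7.9968	121.6102
62	7.6134	109.8500
63	8.9612	108.5309
64	7.7063	116.3964
65	8.8869	107.0130
66	8.0608	129.0463
67	8.8735	118.1616
68	8.4799	114.6717
69	8.1644	127.1241
70	7.6689	124.0588
71	8.8634	124.2017
72	8.8719	127.3535
73	9.1204	110.3336
74	9.2343	124.9342
75	8.4391	119.1567
76	8.5106	117.9320
77	7.7776	108.5917
78	7.7803	120.1455
79	8.9050	127.5008
80	8.8552	110.5326
81	8.9027	118.7345
82	8.6818	122.0894
83	8.1830	124.8363
84	7.5111	110.4605
85	9.2141	119.5935
86	8.9963	110.7087
87	7.8910	113.2661
88	8.4121	109.8900
89	8.6411	108.4408
90	9.1444	112.1217
91	7.5144	114.2817
92	7.9878	126.5073
93	8.2917	109.0436
94	9.0198	114.3078
95	9.0540	113.8154
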