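# residue dH_ppm dN_ppm
1	7.8024	112.0652
2	8.9625	113.8372
3	8.1916	113.2999
4	8.0813	110.3876
5	8.5961	122.3010
6	8.5910	124.3048
7	7.7135	122.3691
8	8.0309	110.9574
9	8.5410	123.1182
10	8.6287	120.5900
11	8.0585	114.4736
12	8.6481	105.4588
13	8.3084	117.3014
14	8.1543	107.2281
15	9.0735	113.4683
16	8.9992	113.8608
17	7.7058	107.9051
18	8.7684	109.6230
19	9.0930	109.6494
20	8.0005	127.8796
21	7.9176	122.8313
22	7.5248	125.6882
23	7.7495	121.9491
24	7.6462	111.1926
25	7.9188	117.1509
26	8.9134	123.2099
27	8.5760	125.6553
28	9.1457	125.6245
29	8.5291	110.7952
30	8.8800	120.3884
31	8.1855	116.2972
32	8.1633	121.2864
34	8.3235	127.1301
35	7.9581	113.7694
36	8.1092	113.5856
37	9.1162	117.9402
38	7.8485	114.1783
39	8.4525	109.5015
40	7.5844	127.0550
41	8.1637	117.2051
42	9.2238	107.4226
43	7.8015	108.6721
44	8.5322	119.7108
45	8.2537	119.0149
46	7.9789	117.7253
47	7.5791	113.7630
48	7.7000	122.2929
49	8.0581	126.8005
50	8.9353	126.3118
51	7.9105	112.4440
52	7.8901	120.5329
53	9.0721	125.9628
54	9.2835	120.2271
55	8.9983	110.8051
56	9.1430	124.4368
57	8.3646	109.0084
58	7.9163	127.3598
59	7.7232	113.4076
60	8.0083	121.6066
62	7.5999	109.8368
63	8.9421	108.4935
64	7.7014	116.4909
65	8.8692	106.9172
66	8.0423	128.9565
67	8.5617	119.1088
68	8.4126	116.5381
69	8.1318	125.2585
70	7.8920	122.6619
71	8.8655	124.2259
72	8.8791	127.3939
73	9.1181	110.2801
74	9.2409	124.9099
75	8.4240	119.1437
76	8.4836	117.9562
77	7.8024	108.5778
78	7.7941	120.0614
79	8.9163	127.5139
80	8.8639	110.4499
81	8.9130	118.7709
82	8.6757	122.1090
83	8.1938	124.7451
84	7.5041	110.5124
85	9.2191	119.6307
86	9.0124	110.7103
87	7.8713	113.3462
88	8.4052	109.8213
89	8.6338	108.4614
90	9.1616	112.3317
91	7.5092	114.1736
92	7.9814	126.5196
93	8.2755	109.0398
94	8.9686	114.3888
95	9.0783	113.7323
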