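injection	dv_uL	heat_ucal
1	1.0000	-4.053136
2	1.0000	-3.783243
3	1.0000	-3.648067
4	1.0000	-3.227573
5	1.0000	-3.097275
6	1.0000	-2.955764
7	1.0000	-2.619535
8	1.0000	-2.373835
9	1.0000	-2.170527
10	1.0000	-2.036744
11	1.0000	-1.700827
12	1.0000	-1.615204
13	1.0000	-1.536075
14	1.0000	-1.518733
15	1.0000	-1.120973
16	1.0000	-1.097841
17	1.0000	-0.991258
18	1.0000	-0.821474
19	1.0000	-0.748571
20	1.0000	-0.693153
21	1.0000	-0.601584
22	1.0000	-0.554132
23	1.0000	-0.558665
24	1.0000	-0.677328
25	1.0000	-0.426742
26	1.0000	-0.443457
27	1.0000	-0.417817
28	1.0000	-0.492808
29	1.0000	-0.386004
30	1.0000	-0.289533
31	1.0000	-0.191797
32	1.0000	-0.288432
33	1.0000	-0.230620
34	1.0000	-0.249045
35	1.0000	-0.339518
36	1.0000	-0.248330
37	1.0000	-0.233672
38	1.0000	-0.194903
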