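age,qx
0,0.00799639
1,0.00295692
2,0.00127603
3,0.000718391
4,0.00053547
5,0.00047763
6,0.000461749
7,0.000460185
8,0.000463772
9,0.000469499
10,0.000476408
11,0.000484227
12,0.000492921
13,0.000502537
14,0.000513155
15,0.000524875
16,0.000537808
17,0.00055208
18,0.000567829
19,0.000585209
20,0.000604387
21,0.00062555
22,0.000648903
23,0.000674673
24,0.000703109
25,0.000734488
26,0.000769115
27,0.000807324
28,0.000849487
29,0.000896012
30,0.00094735
31,0.001004
32,0.00106651
33,0.00113549
34,0.0012116
35,0.00129558
36,0.00138825
37,0.0014905
38,0.00160332
39,0.00172781
40,0.00186516
41,0.00201671
42,0.00218392
43,0.00236841
44,0.00257196
45,0.00279653
46,0.00304428
47,0.00331761
48,0.00361915
49,0.00395179
50,0.00431874
51,0.00472351
52,0.00517
53,0.00566247
54,0.00620563
55,0.00680468
56,0.00746531
57,0.00819383
58,0.00899713
59,0.00988283
60,0.0108593
61,0.0119357
62,0.0131222
63,0.0144299
64,0.0158709
65,0.0174586
66,0.0192077
67,0.0211343
68,0.0232558
69,0.0255917
70,0.0281629
71,0.0309923
72,0.0341051
73,0.0375285
74,0.0412922
75,0.0454284
76,0.0499721
77,0.054961
78,0.0604359
79,0.0664407
80,0.0730226
81,0.080232
82,0.0881226
83,0.0967514
84,0.106179
85,0.116468
86,0.127684
87,0.139897
88,0.153175
89,0.16759
90,0.183213
91,0.200113
92,0.218356
93,0.238006
94,0.259116
95,0.281734
96,0.305893
97,0.33161
98,0.358885
99,0.387693
100,1
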