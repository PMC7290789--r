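t_min,ppm
0,0
1,6.4795
2,11.2797
3,14.8358
4,17.4701
5,19.4217
6,20.8675
7,21.9386
8,22.7321
9,23.3199
10,23.7553
11,23.9578
12,24.0749
13,24.1293
14,24.1375
15,24.1119
16,24.0615
17,23.993
18,23.9112
19,23.82
20,23.721800000000002
21,23.6187
22,23.5121
23,23.4031
24,23.2924
25,23.1808
26,23.0685
27,22.9558
28,22.8431
29,22.7305
30,22.6181
31,22.5061
32,22.3943
33,22.283
34,22.1722
35,22.0618
36,21.9519
37,21.8426
38,21.7337
39,21.6254
40,21.5176
41,21.4103
42,21.3035
43,21.1973
44,21.0916
45,20.9864
46,20.8817
47,20.7776
48,20.674
49,20.5709
50,20.4683
51,20.3662
52,20.2646
53,20.1635
54,20.063
55,19.9629
56,19.8633
57,19.7643
58,19.6657
59,19.5676
60,19.47
61,19.3729
62,19.2763
63,19.1801
64,19.0845
65,18.9893
66,18.8946
67,18.8004
68,18.7066
69,18.6133
70,18.5205
71,18.4281
72,18.3362
73,18.2447
74,18.1537
75,18.0632
76,17.9731
77,17.8835
78,17.7943
79,17.7055
80,17.6172
81,17.5293
82,17.4419
83,17.3549
84,17.2684
85,17.1822
86,17.0965
87,17.0113
88,16.9264
89,16.842
90,16.758
91,16.6744
92,16.5913
93,16.5085
94,16.4262
95,16.3442
96,16.2627
97,16.1816
98,16.1009
99,16.0206
100,15.9407
101,15.8612
102,15.7821
103,15.7034
104,15.6251
105,15.5471
106,15.4696
107,15.3924
108,15.3157
109,15.2393
110,15.1633
111,15.0876
112,15.0124
113,14.9375
114,14.863
115,14.7889
116,14.7151
117,14.6417
118,14.5687
119,14.496
120,14.4237
121,14.3518
122,14.2802
123,14.209
124,14.1381
125,14.0676
126,13.9975
127,13.9276
128,13.8582
129,13.7891
130,13.7203
131,13.6519
132,13.5838
133,13.516
134,13.4486
135,13.3815
136,13.3148
137,13.2484
138,13.1823
139,13.1166
140,13.0511
141,12.9861
142,12.9213
143,12.8568
144,12.7927
145,12.7289
146,12.6654
147,12.6023
148,12.5394
149,12.4769
150,12.4146
151,12.3527
152,12.2911
153,12.2298
154,12.1688
155,12.1081
156,12.0477
157,11.9876
158,11.9278
159,11.8684
160,11.8092
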