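energy_kev,weight
10,5.63700e-10
11,4.14393e-08
12,8.45681e-07
13,7.41789e-06
14,3.67019e-05
15,1.21942e-04
16,3.05233e-04
17,6.22221e-04
18,1.08997e-03
19,1.70386e-03
20,2.44202e-03
21,3.27260e-03
22,4.16029e-03
23,5.07174e-03
24,5.97869e-03
25,6.85901e-03
26,7.69667e-03
27,8.48097e-03
28,9.20557e-03
29,9.86751e-03
30,1.04663e-02
31,1.10032e-02
32,1.14805e-02
33,1.19014e-02
34,1.22695e-02
35,1.25883e-02
36,1.28616e-02
37,1.30931e-02
38,1.32863e-02
39,1.34444e-02
40,1.35705e-02
41,1.36675e-02
42,1.37379e-02
43,1.37842e-02
44,1.38086e-02
45,1.38131e-02
46,1.37995e-02
47,1.37693e-02
48,1.37240e-02
49,1.36650e-02
50,1.35935e-02
51,1.35104e-02
52,1.34169e-02
53,1.33138e-02
54,1.32019e-02
55,1.30820e-02
56,1.29548e-02
57,1.28208e-02
58,5.36069e-02
59,8.40193e-02
60,1.23835e-02
61,1.22275e-02
62,1.20669e-02
63,1.19023e-02
64,1.17337e-02
65,1.15617e-02
66,1.13864e-02
67,3.82292e-02
68,1.10268e-02
69,1.87795e-02
70,1.06567e-02
71,1.04681e-02
72,1.02775e-02
73,1.00848e-02
74,9.89026e-03
75,9.69399e-03
76,9.49609e-03
77,9.29666e-03
78,9.09579e-03
79,8.89358e-03
80,8.69009e-03
81,8.48541e-03
82,8.27960e-03
83,8.07273e-03
84,7.86486e-03
85,7.65604e-03
86,7.44632e-03
87,7.23575e-03
88,7.02438e-03
89,6.81224e-03
90,6.59938e-03
91,6.38584e-03
92,6.17165e-03
93,5.95683e-03
94,5.74143e-03
95,5.52546e-03
96,5.30896e-03
97,5.09195e-03
98,4.87446e-03
99,4.65649e-03
100,4.43809e-03
101,4.21926e-03
102,4.00002e-03
103,3.78040e-03
104,3.56040e-03
105,3.34004e-03
106,3.11935e-03
107,2.89832e-03
108,2.67697e-03
109,2.45533e-03
110,2.23339e-03
111,2.01116e-03
112,1.78867e-03
113,1.56591e-03
114,1.34291e-03
115,1.11965e-03
116,8.96165e-04
117,6.72448e-04
118,4.48510e-04
119,2.24359e-04
120,0.00000e+00
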