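energy_kev,weight
10,4.43274e-10
11,3.26324e-08
12,6.66909e-07
13,5.85833e-06
14,2.90286e-05
15,9.65937e-05
16,2.42155e-04
17,4.94408e-04
18,8.67455e-04
19,1.35822e-03
20,1.94986e-03
21,2.61745e-03
22,3.33313e-03
23,4.07047e-03
24,4.80691e-03
25,5.52471e-03
26,6.21088e-03
27,6.85669e-03
28,7.45684e-03
29,8.00871e-03
30,8.51171e-03
31,8.96661e-03
32,9.37512e-03
33,9.73953e-03
34,1.00625e-02
35,1.03469e-02
36,1.05955e-02
37,1.08112e-02
38,1.09967e-02
39,1.11545e-02
40,1.12870e-02
41,1.13965e-02
42,1.14849e-02
43,1.15541e-02
44,1.16060e-02
45,1.16420e-02
46,1.16636e-02
47,1.16720e-02
48,1.16684e-02
49,1.16538e-02
50,1.16291e-02
51,1.15953e-02
52,1.15531e-02
53,1.15032e-02
54,1.14463e-02
55,1.13829e-02
56,1.13137e-02
57,1.12390e-02
58,5.20856e-02
59,8.25596e-02
60,1.09864e-02
61,1.08940e-02
62,1.07978e-02
63,1.06984e-02
64,1.05958e-02
65,1.04904e-02
66,1.03824e-02
67,3.72930e-02
68,1.01590e-02
69,1.79806e-02
70,9.92714e-03
71,9.80835e-03
72,9.68784e-03
73,9.56571e-03
74,9.44207e-03
75,9.31702e-03
76,9.19064e-03
77,9.06301e-03
78,8.93422e-03
79,8.80433e-03
80,8.67340e-03
81,8.54149e-03
82,8.40867e-03
83,8.27499e-03
84,8.14048e-03
85,8.00520e-03
86,7.86919e-03
87,7.73248e-03
88,7.59512e-03
89,7.45714e-03
90,7.31856e-03
91,7.17943e-03
92,7.03976e-03
93,6.89959e-03
94,6.75893e-03
95,6.61782e-03
96,6.47627e-03
97,6.33430e-03
98,6.19193e-03
99,6.04919e-03
100,5.90608e-03
101,5.76263e-03
102,5.61884e-03
103,5.47474e-03
104,5.33034e-03
105,5.18564e-03
106,5.04067e-03
107,4.89542e-03
108,4.74992e-03
109,4.60418e-03
110,4.45819e-03
111,4.31198e-03
112,4.16555e-03
113,4.01890e-03
114,3.87205e-03
115,3.72501e-03
116,3.57777e-03
117,3.43035e-03
118,3.28276e-03
119,3.13499e-03
120,2.98705e-03
121,2.83896e-03
122,2.69071e-03
123,2.54231e-03
124,2.39376e-03
125,2.24507e-03
126,2.09624e-03
127,1.94728e-03
128,1.79819e-03
129,1.64897e-03
130,1.49962e-03
131,1.35016e-03
132,1.20058e-03
133,1.05088e-03
134,9.01072e-04
135,7.51154e-04
136,6.01128e-04
137,4.50998e-04
138,3.00765e-04
139,1.50432e-04
140,0.00000e+00
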