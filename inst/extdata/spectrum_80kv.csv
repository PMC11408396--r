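energy_kev,weight
10,1.16169e-09
11,8.49513e-08
12,1.72436e-06
13,1.50420e-05
14,7.40052e-05
15,2.44463e-04
16,6.08294e-04
17,1.23249e-03
18,2.14556e-03
19,3.33256e-03
20,4.74499e-03
21,6.31604e-03
22,7.97371e-03
23,9.65152e-03
24,1.12943e-02
25,1.28598e-02
26,1.43187e-02
27,1.56521e-02
28,1.68501e-02
29,1.79090e-02
30,1.88302e-02
31,1.96182e-02
32,2.02794e-02
33,2.08216e-02
34,2.12530e-02
35,2.15821e-02
36,2.18174e-02
37,2.19669e-02
38,2.20381e-02
39,2.20382e-02
40,2.19736e-02
41,2.18505e-02
42,2.16743e-02
43,2.14501e-02
44,2.11824e-02
45,2.08754e-02
46,2.05326e-02
47,2.01576e-02
48,1.97531e-02
49,1.93219e-02
50,1.88664e-02
51,1.83888e-02
52,1.78910e-02
53,1.73750e-02
54,1.68423e-02
55,1.62944e-02
56,1.57325e-02
57,1.51579e-02
58,5.54979e-02
59,8.54592e-02
60,1.33678e-02
61,1.27519e-02
62,1.21277e-02
63,1.14958e-02
64,1.08569e-02
65,1.02114e-02
66,9.55993e-03
67,3.59241e-02
68,8.24067e-03
69,1.55102e-02
70,6.90220e-03
71,6.22660e-03
72,5.54715e-03
73,4.86410e-03
74,4.17769e-03
75,3.48815e-03
76,2.79568e-03
77,2.10046e-03
78,1.40267e-03
79,7.02471e-04
80,0.00000e+00
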