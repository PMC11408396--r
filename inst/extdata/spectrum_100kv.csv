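energy_kev,weight
10,7.65642e-10
11,5.61698e-08
12,1.14391e-06
13,1.00125e-05
14,4.94321e-05
15,1.63875e-04
16,4.09266e-04
17,8.32363e-04
18,1.45464e-03
19,2.26843e-03
20,3.24314e-03
21,4.33523e-03
22,5.49692e-03
23,6.68350e-03
24,7.85734e-03
25,8.98931e-03
26,1.00585e-02
27,1.10513e-02
28,1.19598e-02
29,1.27806e-02
30,1.35138e-02
31,1.41614e-02
32,1.47271e-02
33,1.52154e-02
34,1.56314e-02
35,1.59804e-02
36,1.62676e-02
37,1.64981e-02
38,1.66767e-02
39,1.68079e-02
40,1.68961e-02
41,1.69450e-02
42,1.69583e-02
43,1.69392e-02
44,1.68909e-02
45,1.68159e-02
46,1.67168e-02
47,1.65956e-02
48,1.64543e-02
49,1.62948e-02
50,1.61187e-02
51,1.59273e-02
52,1.57221e-02
53,1.55043e-02
54,1.52749e-02
55,1.50349e-02
56,1.47853e-02
57,1.45269e-02
58,5.51865e-02
59,8.54707e-02
60,1.37051e-02
61,1.34177e-02
62,1.31244e-02
63,1.28258e-02
64,1.25221e-02
65,1.22139e-02
66,1.19014e-02
67,3.86061e-02
68,1.12648e-02
69,1.88778e-02
70,1.06145e-02
71,1.02849e-02
72,9.95245e-03
73,9.61746e-03
74,9.28006e-03
75,8.94041e-03
76,8.59866e-03
77,8.25494e-03
78,7.90937e-03
79,7.56205e-03
80,7.21310e-03
81,6.86261e-03
82,6.51068e-03
83,6.15737e-03
84,5.80278e-03
85,5.44697e-03
86,5.09000e-03
87,4.73195e-03
88,4.37287e-03
89,4.01281e-03
90,3.65182e-03
91,3.28996e-03
92,2.92726e-03
93,2.56376e-03
94,2.19951e-03
95,1.83454e-03
96,1.46888e-03
97,1.10257e-03
98,7.35633e-04
99,3.68101e-04
100,0.00000e+00
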