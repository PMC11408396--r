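material,energy_kev,mu_rho,muen_rho,f_photoelectric,f_compton,f_rayleigh
air,10,5.1200,4.74200,0.8549731,0.03760502,0.1074219
air,15,1.6140,1.33400,0.6969776,0.11714881,0.1858736
air,20,0.7779,0.53890,0.5169317,0.23882095,0.2442473
air,30,0.3538,0.15370,0.2238038,0.50768288,0.2685133
air,40,0.2485,0.06833,0.0584311,0.70012021,0.2414487
air,50,0.2080,0.04098,0.0000000,0.80075885,0.1992411
air,60,0.1875,0.03041,0.0000000,0.83675457,0.1632454
air,80,0.1662,0.02407,0.0000000,0.88604378,0.1139562
air,100,0.1541,0.02325,0.0000000,0.91647577,0.0835242
air,150,0.1356,0.02496,0.0000000,0.95012696,0.0498730
water,10,5.3290,4.94400,0.8434794,0.04017608,0.1163445
water,15,1.6730,1.37400,0.6710990,0.12567330,0.2032277
water,20,0.8096,0.55030,0.4792705,0.25516624,0.2655632
water,30,0.3756,0.15570,0.1806920,0.53176811,0.2875399
water,40,0.2683,0.06947,0.0254850,0.72106740,0.2534476
water,50,0.2269,0.04223,0.0000000,0.79635326,0.2036467
water,60,0.2059,0.03190,0.0000000,0.83325071,0.1667493
water,80,0.1837,0.02597,0.0000000,0.88260502,0.1173950
water,100,0.1707,0.02546,0.0000000,0.91399282,0.0860072
water,150,0.1505,0.02764,0.0000000,0.94881305,0.0511869
lung,10,5.3460,4.96300,0.8443097,0.03971573,0.1159746
lung,15,1.6820,1.38300,0.6738970,0.12396272,0.2021403
lung,20,0.8146,0.55390,0.4845729,0.25149390,0.2639332
lung,30,0.3779,0.15660,0.1900679,0.52414219,0.2857899
lung,40,0.2696,0.06978,0.0361436,0.71163088,0.2522255
lung,50,0.2279,0.04237,0.0000000,0.79499744,0.2050026
lung,60,0.2067,0.03198,0.0000000,0.83208875,0.1679113
lung,80,0.1844,0.02601,0.0000000,0.88173816,0.1182618
lung,100,0.1713,0.02548,0.0000000,0.91333497,0.0866650
lung,150,0.1510,0.02766,0.0000000,0.94840650,0.0515935
soft_tissue,10,5.3790,4.98700,0.8453022,0.03943478,0.1152631
soft_tissue,15,1.6930,1.38800,0.6761321,0.12304095,0.2008269
soft_tissue,20,0.8205,0.55500,0.4885150,0.24944961,0.2620353
soft_tissue,30,0.3783,0.15650,0.1914189,0.52309339,0.2854877
soft_tissue,40,0.2694,0.06962,0.0361008,0.71148646,0.2524128
soft_tissue,50,0.2276,0.04227,0.0000000,0.79484337,0.2051566
soft_tissue,60,0.2064,0.03192,0.0000000,0.83195666,0.1680433
soft_tissue,80,0.1841,0.02599,0.0000000,0.88163957,0.1183604
soft_tissue,100,0.1710,0.02547,0.0000000,0.91326014,0.0867399
soft_tissue,150,0.1508,0.02765,0.0000000,0.94836024,0.0516398
bone,10,28.5100,26.80000,0.9246387,0.00696425,0.0683971
bone,15,9.0320,8.38800,0.8621586,0.02158804,0.1162533
bone,20,4.0010,3.60100,0.7871580,0.04788323,0.1649588
bone,30,1.3310,1.07000,0.6129017,0.13916438,0.2479339
bone,40,0.6655,0.45070,0.4223691,0.26959184,0.3080391
bone,50,0.4242,0.23360,0.2525423,0.41035254,0.3371051
bone,60,0.3148,0.14000,0.1227877,0.53731393,0.3398983
bone,80,0.2229,0.06896,0.0000000,0.70843233,0.2915677
bone,100,0.1855,0.04585,0.0000000,0.77637267,0.2236273
bone,150,0.1480,0.03183,0.0000000,0.86208730,0.1379127
aluminium,10,26.2300,25.43000,0.9281039,0.00708480,0.0648113
aluminium,15,7.9550,7.48700,0.8614085,0.02294094,0.1156505
aluminium,20,3.4410,3.09400,0.7793343,0.05211005,0.1685557
aluminium,30,1.1280,0.87780,0.5892158,0.15369197,0.2570922
aluminium,40,0.5685,0.36010,0.3879991,0.29537822,0.3166227
aluminium,50,0.3681,0.18400,0.2150969,0.44260480,0.3422983
aluminium,60,0.2778,0.10990,0.0917453,0.56988172,0.3383729
aluminium,80,0.2018,0.05511,0.0000000,0.72127692,0.2787231
aluminium,100,0.1704,0.03794,0.0000000,0.78568178,0.2143182
aluminium,150,0.1378,0.02827,0.0000000,0.87137255,0.1286275
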