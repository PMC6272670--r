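compound,slope,intercept,r2,range_low_ng,range_high_ng,lod_ng,loq_ng,intraday_rsd,interday_rsd
1,0.9845,-3.0467,1.0000,36.18,1266.30,4.27,8.54,0.33,1.70
2,1.2843,-12.4895,1.0000,91.80,3213.00,9.00,18.01,0.44,0.15
3,1.0255,-11.8232,0.9999,39.03,1366.05,8.37,18.30,0.42,0.41
4,0.8371,-4.3034,1.0000,46.29,1620.15,4.99,14.97,0.33,0.26
5,1.1938,-4.7773,1.0000,86.31,3020.85,1.39,6.95,0.17,0.47
6,0.9789,-15.6369,1.0000,91.60,3206.00,6.25,27.49,0.44,0.85
7,1.8986,12.2728,1.0000,280.56,9819.60,2.94,12.73,0.28,0.42
8,1.0888,-3.4518,1.0000,107.38,3758.30,7.93,31.74,0.24,0.46
9,1.7141,-29.0498,1.0000,61.05,2136.75,8.06,24.93,0.22,0.41
10,1.2220,-1.4093,1.0000,86.40,3024.00,7.72,24.95,0.31,0.85
11,1.0257,-24.0442,0.9997,49.50,1732.50,1.24,3.71,0.19,0.48
12,2.1915,-41.1740,1.0000,125.20,4382.00,3.13,10.42,0.22,0.43
13,1.5909,-0.0134,1.0000,12.35,432.25,4.06,13.95,0.17,2.87
14,1.7761,-4.4637,0.9999,22.76,796.43,3.35,11.18,0.75,2.22
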