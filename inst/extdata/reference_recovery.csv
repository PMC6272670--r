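compound,repeatability_rsd,stability_rsd,original_ug,spiked_ug,observed_ug,recovery_mean,recovery_rsd
1,0.71,1.51,163.01,164.02,329.03,101.22,1.02
2,0.46,0.31,343.80,362.30,706.23,100.04,0.24
3,2.94,0.85,127.43,143.63,273.94,102.01,1.87
4,0.89,2.08,170.29,175.29,344.42,99.33,0.45
5,0.41,1.23,375.40,335.38,718.15,102.20,0.75
6,2.07,2.78,483.13,474.85,946.76,97.64,1.09
7,0.52,0.28,1325.26,1242.48,2542.17,97.94,0.34
8,0.70,1.19,224.28,257.71,478.29,98.56,0.38
9,0.90,1.03,198.16,234.43,429.08,98.51,0.17
10,0.76,2.21,421.27,421.63,858.20,103.63,0.39
11,1.47,0.80,292.02,277.20,575.80,102.37,0.30
12,1.12,0.26,439.82,420.67,859.56,99.78,0.27
13,2.70,1.14,15.88,20.75,36.93,101.43,0.71
14,1.98,1.00,89.00,87.38,174.48,96.68,0.48
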