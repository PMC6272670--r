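batch,c1,c2,c3,c4,c5,c6,c7,c8,c9,c10,c11,c12,c13,c14,sum_printed
Y2-1,0.785,1.706,0.667,0.758,1.949,2.121,6.602,1.130,0.932,2.184,1.388,2.041,0.092,0.405,22.761
Y2-2,1.355,4.712,1.397,1.639,2.643,5.294,11.301,2.136,0.966,2.678,1.440,1.833,0.116,0.423,37.934
Y2-3,1.068,3.394,2.013,1.757,1.533,5.627,7.218,1.808,0.313,3.166,0.584,0.917,0.048,0.348,29.795
Y2-4,0.706,1.032,0.735,0.306,0.333,1.172,2.777,0.314,1.043,1.155,1.171,2.222,0.147,0.303,13.415
Y2-5,0.989,2.491,1.113,0.540,1.327,2.408,8.054,1.040,1.517,2.579,1.498,3.505,0.159,0.484,27.703
Y2-6,1.000,3.984,0.622,0.563,1.378,2.113,8.742,0.814,1.932,0.570,1.409,3.422,0.303,0.259,27.112
Y2-7,1.402,3.601,1.427,1.585,2.748,4.234,10.339,1.769,1.116,2.047,1.554,2.255,0.161,0.413,34.650
Y2-8,1.080,4.098,1.108,1.742,2.698,5.124,10.344,2.377,0.955,2.256,1.383,2.003,0.131,0.453,35.751
Y2-9,0.676,1.029,0.862,0.616,1.314,1.829,4.505,0.805,1.381,1.839,2.251,4.168,0.210,0.664,22.148
Y2-10,0.927,4.273,1.931,2.174,1.625,6.832,8.613,2.021,0.471,3.789,0.865,1.314,0.056,0.573,35.464
Y2-11,0.805,3.544,1.234,1.105,1.414,3.796,7.718,1.280,1.262,1.878,0.847,1.534,0.099,0.442,26.958
Y2-12,0.397,0.984,0.779,0.608,0.606,1.364,3.054,0.677,1.267,0.701,2.360,3.906,0.247,1.644,18.594
Y2-13,0.827,2.164,1.239,1.070,1.498,2.774,7.275,1.045,2.546,1.484,3.102,5.335,0.348,0.900,31.607
Y2-14,0.616,0.998,0.895,0.660,1.398,1.744,4.775,0.943,1.341,1.736,2.279,4.352,0.206,0.810,22.752
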