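Well,Sample,Sample type,Target,Target type,Dye,Cq,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31,32,33,34,35,36,37,38,39,40,41,42,43,44,45
A1,Embryo_1,unkn,SCX,toi,SYBR,33.2,1.3,1.28,1.28,1.27,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2825,1.2826,1.2827,1.2828,1.2831,1.2837,1.2848,1.2868,1.2907,1.298,1.312,1.3384,1.3883,1.4822,1.6571,1.9778,2.5478,3.5083,4.989,6.9862,9.244,11.3393,12.9563,14.0355,14.6877,15.1,15.29,15.34,15.43
A2,Embryo_2,unkn,SCX,toi,SYBR,33.8,1.28,1.32,1.3,1.26,1.29,1.29,1.29,1.29,1.29,1.29,1.29,1.29,1.29,1.29,1.29,1.29,1.29,1.2901,1.2901,1.2902,1.2904,1.2907,1.2914,1.2927,1.2951,1.2997,1.3084,1.3248,1.356,1.4149,1.5252,1.7298,2.101,2.749,3.8079,5.3642,7.3287,9.3824,11.1467,12.4244,13.2396,13.65,14.02,14.16,14.21
A3,Embryo_3,unkn,SCX,toi,SYBR,32,1.53,1.53,1.54,1.51,1.5275,1.5275,1.5275,1.5275,1.5275,1.5275,1.5275,1.5275,1.5275,1.5275,1.5275,1.5276,1.5276,1.5277,1.5279,1.5282,1.5289,1.5301,1.5324,1.5369,1.5453,1.5614,1.5917,1.649,1.7566,1.9567,2.3216,2.9648,4.0329,5.6423,7.7439,10.0293,12.0691,13.5926,14.5859,15.1774,15.5107,15.44,15.62,15.79,15.87
A4,Embryo_4,unkn,SCX,toi,SYBR,34.3,1.44,1.44,1.43,1.42,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4326,1.4327,1.4328,1.4331,1.4336,1.4345,1.4363,1.4398,1.4464,1.4589,1.4825,1.5271,1.6112,1.7681,2.0562,2.5704,3.4426,4.8019,6.6639,8.8094,10.8402,12.4342,13.5114,13.81,14.29,14.64,14.86
A5,Embryo_5,unkn,SCX,toi,SYBR,31.9,1.45,1.45,1.43,1.4,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4325,1.4326,1.4326,1.4327,1.4329,1.4333,1.434,1.4353,1.4378,1.4426,1.4518,1.469,1.5018,1.5636,1.6795,1.8947,2.2863,2.9734,4.1054,5.7903,7.954,10.2611,12.2811,13.7663,14.7241,15.2904,15.6083,15.42,15.7,15.74,15.95
A6,Embryo_6,unkn,SCX,toi,SYBR,32.6,1.47,1.47,1.47,1.44,1.4625,1.4625,1.4625,1.4625,1.4625,1.4625,1.4625,1.4625,1.4625,1.4625,1.4625,1.4625,1.4626,1.4626,1.4627,1.463,1.4634,1.4642,1.4657,1.4686,1.4742,1.4846,1.5045,1.542,1.6128,1.7454,1.9902,2.4318,3.1945,4.4192,6.1715,8.3064,10.4512,12.2267,13.4755,14.2567,14.7102,15.02,15.14,15.18,15.21
A7,Embryo_7,unkn,SCX,toi,SYBR,33.1,1.47,1.48,1.46,1.45,1.465,1.465,1.465,1.465,1.465,1.465,1.465,1.465,1.465,1.465,1.465,1.465,1.4651,1.4651,1.4652,1.4654,1.4658,1.4666,1.4681,1.4708,1.476,1.4859,1.5047,1.5402,1.6074,1.7337,1.9687,2.3984,3.1592,4.4319,6.3723,8.9479,11.804,14.4031,16.3759,17.677,18.4573,18.54,18.99,19.17,19.34
A8,Embryo_8,unkn,SCX,toi,SYBR,31.7,1.37,1.34,1.34,1.3,1.3375,1.3375,1.3375,1.3375,1.3375,1.3375,1.3375,1.3375,1.3375,1.3375,1.3375,1.3376,1.3377,1.3378,1.338,1.3385,1.3395,1.3413,1.3446,1.3511,1.3633,1.3864,1.4302,1.5128,1.6675,1.9538,2.4717,3.3714,4.8289,6.943,9.5652,12.2525,14.5184,16.1352,17.1564,17.7527,18.0849,18.15,18.3,18.44,18.44
H9,Adult_9,unkn,cTNI,toi,SYBR,19.4,1.51,1.48,1.49,1.48,1.4902,1.4904,1.4907,1.4913,1.4925,1.4947,1.4989,1.5068,1.522,1.5506,1.6049,1.707,1.8977,2.2487,2.8775,3.9509,5.6413,7.9917,10.7517,13.4162,15.5444,17.0011,17.8961,18.41,18.6936,18.8467,18.9283,18.9716,18.9945,19.0066,19.0129,19.0163,19.0181,19.019,19.0195,19.0197,19.0199,19.01,19.06,18.99,19.02
H10,Adult_10,unkn,cTNI,toi,SYBR,19.8,1.41,1.43,1.44,1.49,1.4426,1.4427,1.443,1.4434,1.4442,1.4457,1.4485,1.4539,1.4642,1.4837,1.5207,1.5903,1.721,1.9631,2.4024,3.1695,4.4229,6.2652,8.5906,11.0216,13.1101,14.6224,15.5874,16.1543,16.4713,16.6438,16.7361,16.7851,16.8111,16.8248,16.832,16.8358,16.8378,16.8388,16.8394,16.8397,16.8398,16.8,16.83,16.78,16.84
H11,Adult_11,unkn,cTNI,toi,SYBR,19.4,1.43,1.44,1.48,1.47,1.4552,1.4553,1.4556,1.4561,1.457,1.4589,1.4624,1.469,1.4816,1.5055,1.5506,1.6355,1.7942,2.0862,2.6094,3.5025,4.9089,6.8644,9.1607,11.3777,13.1483,14.3603,15.1049,15.5325,15.7684,15.8958,15.9637,15.9998,16.0188,16.0288,16.0341,16.0369,16.0384,16.0392,16.0396,16.0398,16.0399,16.13,16.09,16.03,16.04
H12,Adult_12,unkn,cTNI,toi,SYBR,19,1.52,1.5,1.53,1.5,1.5127,1.5129,1.5133,1.514,1.5154,1.5179,1.5228,1.5321,1.5497,1.583,1.6459,1.764,1.9836,2.3842,3.0903,4.2627,6.0293,8.3363,10.845,13.084,14.7564,15.8468,16.496,16.8619,17.0618,17.169,17.2261,17.2563,17.2723,17.2807,17.2851,17.2874,17.2886,17.2893,17.2896,17.2898,17.2899,17.35,17.29,17.27,17.29
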