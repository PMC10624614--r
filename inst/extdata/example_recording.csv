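t_s,MABP,HbD,BFI
0,44.776,10.2327,1.53405e-08
1,45.034,10.1730,1.51997e-08
2,45.874,10.2176,1.52860e-08
3,45.403,10.1757,1.53374e-08
4,45.549,10.1959,1.56672e-08
5,46.304,10.3578,1.53061e-08
6,45.921,10.3954,1.54509e-08
7,45.346,10.3776,1.54373e-08
8,45.689,10.4847,1.52896e-08
9,45.893,10.6162,1.54299e-08
10,46.665,10.3791,1.56621e-08
11,46.419,10.2127,1.55163e-08
12,46.529,10.5578,1.54561e-08
13,46.502,10.3981,1.53861e-08
14,46.319,10.4102,1.51393e-08
15,47.333,10.5896,1.56131e-08
16,46.888,10.4647,1.52186e-08
17,45.966,10.3753,1.55412e-08
18,47.090,10.5177,1.57075e-08
19,46.670,10.4860,1.51938e-08
20,46.475,10.4987,1.55032e-08
21,46.850,10.5330,1.53446e-08
22,46.554,10.4518,1.51326e-08
23,46.693,10.5457,1.51243e-08
24,46.746,10.4498,1.50929e-08
25,46.325,10.4937,1.52339e-08
26,47.331,10.5571,1.50734e-08
27,47.046,10.4760,1.53738e-08
28,46.509,10.3833,1.55625e-08
29,47.439,10.5125,1.50303e-08
30,47.073,10.4772,1.53166e-08
31,46.742,10.4114,1.52880e-08
32,47.168,10.3577,1.51961e-08
33,47.104,10.2470,1.49680e-08
34,47.017,10.4206,1.50738e-08
35,46.893,10.1981,1.50218e-08
36,46.763,10.4495,1.51203e-08
37,46.433,10.3557,1.49517e-08
38,46.247,10.1497,1.51258e-08
39,46.123,10.0409,1.48949e-08
40,45.898,10.0421,1.50810e-08
41,45.988,10.1081,1.47381e-08
42,45.457,10.0266,1.46791e-08
43,46.719,9.9852,1.53276e-08
44,46.219,9.8933,1.47527e-08
45,45.169,9.9526,1.48346e-08
46,45.336,9.8474,1.48608e-08
47,45.188,9.7282,1.46691e-08
48,45.563,9.8265,1.47966e-08
49,45.092,9.9265,1.47529e-08
50,45.101,9.7478,1.46449e-08
51,44.863,9.8376,1.46679e-08
52,44.732,9.5873,1.46353e-08
53,45.173,9.7169,1.49434e-08
54,44.412,9.7488,1.44982e-08
55,44.989,9.7026,1.44317e-08
56,43.644,9.6600,1.45901e-08
57,44.382,9.5637,1.46210e-08
58,44.086,9.5225,1.46316e-08
59,44.015,9.4864,1.44907e-08
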