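"age","sex","qx","cv_fraction"
40,"male",0.0016088,0.22
41,"male",0.0017156,0.2215
42,"male",0.00183268,0.223
43,"male",0.00196102,0.2245
44,"male",0.00210171,0.226
45,"male",0.00225593,0.2275
46,"male",0.00242499,0.229
47,"male",0.00261031,0.2305
48,"male",0.00281344,0.232
49,"male",0.00303611,0.2335
50,"male",0.00328017,0.235
51,"male",0.00354768,0.2365
52,"male",0.00384089,0.238
53,"male",0.00416226,0.2395
54,"male",0.00451447,0.241
55,"male",0.00490049,0.2425
56,"male",0.00532353,0.244
57,"male",0.00578713,0.2455
58,"male",0.00629515,0.247
59,"male",0.00685183,0.2485
60,"male",0.0074618,0.25
61,"male",0.00813012,0.2515
62,"male",0.00886232,0.253
63,"male",0.00966446,0.2545
64,"male",0.0105432,0.256
65,"male",0.0115056,0.2575
66,"male",0.0125598,0.259
67,"male",0.0137142,0.2605
68,"male",0.0149783,0.262
69,"male",0.0163624,0.2635
70,"male",0.0178777,0.265
71,"male",0.0195362,0.2665
72,"male",0.0213514,0.268
73,"male",0.0233376,0.2695
74,"male",0.0255106,0.271
75,"male",0.0278875,0.2725
76,"male",0.0304867,0.274
77,"male",0.0333284,0.2755
78,"male",0.0364344,0.277
79,"male",0.0398282,0.2785
80,"male",0.0435353,0.28
81,"male",0.0475832,0.2815
82,"male",0.0520016,0.283
83,"male",0.0568221,0.2845
84,"male",0.062079,0.286
85,"male",0.0678088,0.2875
86,"male",0.0740506,0.289
87,"male",0.0808458,0.2905
88,"male",0.0882385,0.292
89,"male",0.0962754,0.2935
90,"male",0.105005,0.295
91,"male",0.11448,0.2965
92,"male",0.124752,0.298
93,"male",0.135877,0.2995
94,"male",0.147911,0.301
95,"male",0.160913,0.3025
96,"male",0.17494,0.304
97,"male",0.190049,0.3055
98,"male",0.206297,0.307
99,"male",0.223736,0.3085
100,"male",0.242415,0.31
101,"male",0.262378,0.3115
102,"male",0.283661,0.313
103,"male",0.30629,0.3145
104,"male",0.330279,0.316
105,"male",0.355627,0.3175
106,"male",0.382317,0.319
107,"male",0.41031,0.3205
108,"male",0.439545,0.322
109,"male",0.469934,0.3235
110,"male",1,0.325
40,"female",0.00104386,0.22
41,"female",0.00111879,0.2215
42,"female",0.00120125,0.223
43,"female",0.00129202,0.2245
44,"female",0.00139193,0.226
45,"female",0.00150189,0.2275
46,"female",0.00162291,0.229
47,"female",0.00175612,0.2305
48,"female",0.00190272,0.232
49,"female",0.00206407,0.2335
50,"female",0.00224165,0.235
51,"female",0.00243708,0.2365
52,"female",0.00265217,0.238
53,"female",0.00288887,0.2395
54,"female",0.00314935,0.241
55,"female",0.003436,0.2425
56,"female",0.00375144,0.244
57,"female",0.00409855,0.2455
58,"female",0.00448049,0.247
59,"female",0.00490074,0.2485
60,"female",0.00536314,0.25
61,"female",0.00587188,0.2515
62,"female",0.00643157,0.253
63,"female",0.0070473,0.2545
64,"female",0.00772463,0.256
65,"female",0.00846966,0.2575
66,"female",0.00928913,0.259
67,"female",0.0101904,0.2605
68,"female",0.0111815,0.262
69,"female",0.0122713,0.2635
70,"female",0.0134695,0.265
71,"female",0.0147868,0.2665
72,"female",0.0162348,0.268
73,"female",0.0178263,0.2695
74,"female",0.0195751,0.271
75,"female",0.0214965,0.2725
76,"female",0.0236071,0.274
77,"female",0.0259252,0.2755
78,"female",0.0284705,0.277
79,"female",0.0312645,0.2785
80,"female",0.0343308,0.28
81,"female",0.0376948,0.2815
82,"female",0.0413842,0.283
83,"female",0.045429,0.2845
84,"female",0.0498616,0.286
85,"female",0.0547171,0.2875
86,"female",0.0600331,0.289
87,"female",0.0658501,0.2905
88,"female",0.0722117,0.292
89,"female",0.0791642,0.2935
90,"female",0.086757,0.295
91,"female",0.0950425,0.2965
92,"female",0.104076,0.298
93,"female",0.113915,0.2995
94,"female",0.124621,0.301
95,"female",0.136256,0.3025
96,"female",0.148885,0.304
97,"female",0.162573,0.3055
98,"female",0.177386,0.307
99,"female",0.193388,0.3085
100,"female",0.210643,0.31
101,"female",0.22921,0.3115
102,"female",0.249144,0.313
103,"female",0.27049,0.3145
104,"female",0.293286,0.316
105,"female",0.317557,0.3175
106,"female",0.34331,0.319
107,"female",0.370536,0.3205
108,"female",0.399202,0.322
109,"female",0.429249,0.3235
110,"female",1,0.325
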