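age,qx_male,qx_female
0,7.69970355760652e-05,4.23491032514045e-05
1,7.96428283414974e-05,4.38043405618371e-05
2,8.25479007345864e-05,4.54021886894251e-05
3,8.57376605006843e-05,4.71566229927056e-05
4,8.92400050038766e-05,4.90829883121879e-05
5,9.30855651386508e-05,5.11981331586808e-05
6,9.73079731318993e-05,5.35205570468822e-05
7,0.000101944156571498,5.60705722633115e-05
8,0.000107034661228633,5.88704814808994e-05
9,0.000112624005492168,6.19447727717715e-05
10,0.00011876106950659,6.53203337225294e-05
11,0.00012549952240859,6.90266865215339e-05
12,0.000132898291389072,7.30962460714357e-05
13,0.000141022076670216,7.75646033805977e-05
14,0.000149941916884555,8.24708367072047e-05
15,0.000159735809785566,8.78578531725571e-05
16,0.000170489393693019,9.37727638234964e-05
17,0.00018229669560843,0.000100267295417567
18,0.000195260952508658,0.000107398242521484
19,0.000209495512964342,0.000115227963866205
20,0.000225124826917944,0.000123824927284355
21,0.000242285532223274,0.000133264307980663
22,0.00026112764737829,0.000143628645344673
23,0.000281815880800895,0.000155008564028059
24,0.000304531067995661,0.000167503565559612
25,0.00032947174906206,0.000181222897388422
26,0.000356855900191189,0.000196286506907839
27,0.000386922834120118,0.000212826088754947
28,0.000419935285950968,0.000230986234476926
29,0.000456181702317426,0.000250925694545323
30,0.000495978753613291,0.000272818763659033
31,0.000539674090875963,0.000296856801341505
32,0.000587649370986765,0.000323249900993305
33,0.000640323576102109,0.000352228721832937
34,0.000698156655687621,0.000384046499552038
35,0.000761653522219463,0.000418981253026862
36,0.000831368434541457,0.000457338206102165
37,0.000907909806064366,0.000499452445275161
38,0.000991945478472811,0.000545691836108642
39,0.00108420850538893,0.000596460223370676
40,0.00118550349456159,0.000652200942280357
41,0.00129671356161909,0.000713400670833142
42,0.00141880795327509,0.000780593656010353
43,0.00155285040312958,0.000854366349766211
44,0.00170000828889449,0.000935362494049019
45,0.00186156266600923,0.00102428869777682
46,0.00203891925922672,0.00112192055266869
47,0.0022336205008715,0.00122910933916531
48,0.00244735871209811,0.00134678937836619
49,0.00268199053165097,0.00147598609100508
50,0.00293955270533475,0.0016178248299985
51,0.00322227935865194,0.00177354055905343
52,0.00353262088485495,0.00194448845625184
53,0.0038732645909515,0.0021321555284407
54,0.00424715725496905,0.00233817332968755
55,0.00465752975896128,0.00256433188501359
56,0.00510792397373527,0.00281259492911545
57,0.00560222208297356,0.0030851165788206
58,0.0061446785461563,0.00338425956760091
59,0.00673995491123636,0.00371261518056432
60,0.00739315769911197,0.00407302503893336
61,0.00810987959221399,0.00446860489404244
62,0.00889624416853274,0.00490277060226652
63,0.00975895442959607,0.00537926646393172
64,0.010705345375562,0.00590219612099474
65,0.0117434408818653,0.0064760562199303
66,0.0128820151286787,0.00710577305757487
67,0.0141306588255543,0.00779674243831752
68,0.0154998504574037,0.0085548729805982
69,0.0170010327526096,0.00938663311865517
70,0.0186466945372346,0.0102991020512057
71,0.0204504580883291,0.0113000248914692
72,0.0224271720310028,0.0123978722716636
73,0.0245930097344191,0.0136019046486292
74,0.0269655730467255,0.0149222415441294
75,0.0295640010629012,0.0163699359318632
76,0.0324090834365464,0.0179570539512255
77,0.0355233775197183,0.0196967600828135
78,0.0389313283360935,0.0216034078596189
79,0.0426593900529172,0.0236926361071861
80,0.0467361472063382,0.0259814706015672
81,0.0511924334416548,0.0284884309007354
82,0.0560614449427114,0.031233641937514
83,0.0613788450304662,0.0342389497533977
84,0.067182855596594,0.0375280404953202
85,0.0735143300911986,0.0411265614828114
86,0.0804168016927659,0.0450622427714278
87,0.087936499044278,0.0493650171790916
88,0.0961223205369521,0.0540671361933397
89,0.105025756563782,0.0592032785270012
90,0.114700747459794,0.0648106473245289
91,0.125203463018791,0.0709290511282051
92,0.136591987569666,0.0776009626806257
93,0.148925892675522,0.0848715484569738
94,0.162265677683744,0.0927886604808099
95,0.176672056742422,0.101402780478976
96,0.192205069695032,0.110766904781476
97,0.208922993717293,0.120936356589183
98,0.226881032983267,0.131968510350443
99,0.246129765435363,0.143922411063178
100,0.266713329361957,0.15685826943648
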