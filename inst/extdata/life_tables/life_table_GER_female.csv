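age,qx
0,0.000508126504011885
1,0.000509040026562824
2,0.000510054684774275
3,0.00051118167520825
4,0.000512433433951354
5,0.000513823773831357
6,0.000515368036820951
7,0.000517083263311902
8,0.000518988380124208
9,0.000521104409324846
10,0.000523454700158577
11,0.000526065186646552
12,0.000528964673694787
13,0.000532185154863862
14,0.000535762165305043
15,0.000539735173749167
16,0.000544148017870283
17,0.000549049387818856
18,0.00055449336325053
19,0.000560540009765687
20,0.000567256041325792
21,0.000574715555937466
22,0.000583000852701798
23,0.000592203339214947
24,0.000602424539300817
25,0.000613777212151501
26,0.000626386595175665
27,0.000640391784201388
28,0.000655947266187784
29,0.000673224621258406
30,0.000692414412716502
31,0.00071372828575067
32,0.000737401297803197
33,0.000763694506089152
34,0.000792897840539042
35,0.000825333293519304
36,0.000861358461101913
37,0.000901370474432506
38,0.000945810363927713
39,0.000995167903657279
40,0.00104998698837699
41,0.00111087160132439
42,0.00117849243712553
43,0.00125359425103422
44,0.00133700401330983
45,0.00142963995588896
46,0.0015325216076898
47,0.0016467809249916
48,0.00177367463440525
49,0.00191459791810433
50,0.00207109958427054
51,0.00224489888022406
52,0.00243790412152423
53,0.00265223332751974
54,0.00289023707245994
55,0.00315452378141401
56,0.0034479877219028
57,0.00377383996535463
58,0.00413564261721455
59,0.00453734664070027
60,0.00498333362666581
61,0.00547846189060475
62,0.00602811730715813
63,0.00663826932215683
64,0.00731553261159101
65,0.00806723488513084
66,0.00890149135783169
67,0.00982728643600472
68,0.010854563180099
69,0.0119943211164767
70,0.0132587229682163
71,0.014661210858855
72,0.0162166325076573
73,0.0179413778748734
74,0.0198535266235107
75,0.0219730066318032
76,0.0243217636074253
77,0.0269239416079928
78,0.0298060739475006
79,0.0329972835471978
80,0.0365294912509844
81,0.0404376299452271
82,0.0447598614727477
83,0.0495377922786472
84,0.0548166824359774
85,0.0606456411332871
86,0.0670777998229326
87,0.0741704519875928
88,0.0819851458441595
89,0.0905877132374344
90,0.100048214462403
91,0.110440774796703
92,0.121843284161516
93,0.134336926646347
94,0.148005501787849
95,0.162934494737425
96,0.179209848165796
97,0.196916385476665
98,0.216135833380119
99,0.236944393095725
100,1
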