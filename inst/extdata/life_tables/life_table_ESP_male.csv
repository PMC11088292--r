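age,qx
0,0.000528961819364904
1,0.00053176471881522
2,0.000534837710139291
3,0.000538206818867626
4,0.000541900578107879
5,0.000545950270112283
6,0.000550390191109251
7,0.000555257941636911
8,0.000560594744832943
9,0.000566445795370685
10,0.000572860641988138
11,0.000579893606842297
12,0.000587604245228857
13,0.000596057849548082
14,0.000605326001770212
15,0.00061548717905946
16,0.000626627417665171
17,0.000638841040674021
18,0.000652231455755992
19,0.000666912029619771
20,0.000683007046537898
21,0.000700652759001885
22,0.000719998539338795
23,0.000741208141959659
24,0.000764461086831147
25,0.000789954175771101
26,0.000817903154264221
27,0.000848544532703666
28,0.000882137582274511
29,0.000918966522137188
30,0.000959342916134531
31,0.00100360829896384
32,0.00105213705362339
33,0.00110533956398773
34,0.00116366566858583
35,0.0012276084440872
36,0.00129770834963894
37,0.00137455776607132
38,0.00145880596711723
39,0.00155116456318605
40,0.00165241346192047
41,0.00176340739376335
42,0.00188508305509216
43,0.00201846692616381
44,0.00216468382617274
45,0.00232496627318157
46,0.00250066472255328
47,0.0026932587638262
48,0.00290436936272243
49,0.00313577224220507
50,0.00338941250418379
51,0.00366742060162517
52,0.0039721297794445
53,0.00430609511161129
54,0.00467211427136749
55,0.00507325018128035
56,0.00551285569994653
57,0.0059946005124466
58,0.00652250040196001
59,0.00710094909012682
60,0.00773475284354086
61,0.00842916805288507
62,0.00918994199931034
63,0.0100233570292271
64,0.0109362783631761
65,0.0119362057661352
66,0.0130313293046502
67,0.0142305894094918
68,0.0155437414498448
69,0.0169814250048161
70,0.0185552379884271
71,0.0202778157430543
72,0.0221629151608768
73,0.0242255038201797
74,0.0264818540297472
75,0.0289496415557796
76,0.0316480486569025
77,0.034597870868197
78,0.0378216267483031
79,0.0413436695271686
80,0.0451902992576937
81,0.0493898736732442
82,0.0539729154748344
83,0.0589722132061153
84,0.0644229122101502
85,0.0703625913882778
86,0.0768313205877579
87,0.0838716924223825
88,0.0915288211725314
89,0.0998503001162188
90,0.108886107214919
91,0.118688447530977
92,0.129311519113518
93,0.140811187400481
94,0.153244551511546
95,0.166669384245136
96,0.181143426273124
97,0.196723514124268
98,0.213464521289222
99,0.231418092454131
100,1
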