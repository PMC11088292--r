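age,qx
0,0.000506223790791238
1,0.000506926664509022
2,0.000507707353225806
3,0.000508574471752121
4,0.000509537588617937
5,0.00051060733165198
6,0.000511795505248158
7,0.000513115220612592
8,0.000514581040428008
9,0.000516209139529877
10,0.000518017483368327
11,0.000520026026221698
12,0.000522256931348886
13,0.000524734815507411
14,0.000527487020532624
15,0.000530543914972315
16,0.000533939229101832
17,0.000537710427010452
18,0.000541899119861577
19,0.000546551524877481
20,0.000551718975106641
21,0.000557458485586859
22,0.000563833382139833
23,0.000570913999717426
24,0.000578778457987483
25,0.000587513522691374
26,0.000597215562248343
27,0.000607991610123482
28,0.000619960544635756
29,0.000633254399168059
30,0.000648019817163226
31,0.000664419667876115
32,0.000682634840599161
33,0.000702866237028643
34,0.000725336983587455
35,0.000750294887915892
36,0.000778015166380208
37,0.000808803472386654
38,0.000842999258532817
39,0.000880979509219504
40,0.000923162884327255
41,0.000970014318957935
42,0.00102205012910628
43,0.00107984367850023
44,0.00114403166778532
45,0.00121532111377676
46,0.00129449709372975
47,0.00138243133753524
48,0.00148009175951258
49,0.00158855303110661
50,0.00170900830637899
51,0.00184278222378964
52,0.00199134532048129
53,0.00215633000916915
54,0.00233954828290284
55,0.00254301132946733
56,0.00276895125509713
57,0.00301984513656617
58,0.00329844164161042
59,0.00360779048008097
60,0.00395127497219883
61,0.00433264804573918
62,0.00475607200081807
63,0.00522616240900631
64,0.00574803654250122
65,0.00632736675865153
66,0.00697043929473118
67,0.00768421895677596
68,0.00847642021355777
69,0.00935558523114499
70,0.0103311694033419
71,0.0114136349465471
72,0.0126145531315964
73,0.0139467157166293
74,0.0154242561198233
75,0.0170627808238163
76,0.018879511428462
77,0.0208934376574685
78,0.0231254814679729
79,0.0255986721987881
80,0.0283383324091266
81,0.0313722736886745
82,0.0347310012425319
83,0.0384479254480323
84,0.0425595778184484
85,0.0471058278610104
86,0.0521300961496185
87,0.0576795575088591
88,0.0638053264854406
89,0.0705626152246766
90,0.0780108514329051
91,0.0862137412560277
92,0.0952392586137689
93,0.105159538790068
94,0.11605064991098
95,0.127992211402571
96,0.141066823731752
97,0.15535926889426
98,0.170955436537992
99,0.187940926752694
100,1
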