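age,qx
0,0.00053503657277576
1,0.000538424844129692
2,0.000542139612449644
3,0.000546212337890983
4,0.000550677511722664
5,0.000555572948311545
6,0.000560940105220453
7,0.000566824434127478
8,0.000573275765529235
9,0.000580348730477853
10,0.000588103222911807
11,0.000596604906486164
12,0.00060592577017482
13,0.000616144737335067
14,0.000627348333367861
15,0.000639631417603148
16,0.000653097985573559
17,0.000667862048433165
18,0.000684048596922282
19,0.000701794657982702
20,0.000721250452906164
21,0.000742580666739934
22,0.000765965839601424
23,0.000791603891565074
24,0.000819711793892286
25,0.000850527400585221
26,0.000884311455567333
27,0.000921349792239234
28,0.000961955743737808
29,0.00100647278394828
30,0.00105527742120126
31,0.00110878236863843
32,0.00116744001746771
33,0.0012317462417667
34,0.00130224456614858
35,0.00137953073049391
36,0.00146425768909464
37,0.00155714108496885
38,0.00165896524381304
39,0.00177058973607636
40,0.00189295655999111
41,0.00202709800310563
42,0.00217414524494475
43,0.00233533776890837
44,0.00251203365741304
45,0.00270572085062071
46,0.00291802945587705
47,0.00315074520223524
48,0.00340582414215396
49,0.00368540871064416
50,0.003991845260787
51,0.00432770320362796
52,0.00469579588994162
53,0.00509920338120395
54,0.00554129726722019
55,0.00602576769814178
56,0.00655665280891671
57,0.00713837072437828
58,0.00777575434293987
59,0.00847408910594327
60,0.00923915396771136
61,0.0100772657878228
62,0.0109953273714654
63,0.0120008793852205
64,0.0131021563734037
65,0.0143081470930653
66,0.0156286593726508
67,0.0170743896785709
68,0.0186569975436656
69,0.0203891849695527
70,0.0222847808584696
71,0.0243588304563334
72,0.0266276896937007
73,0.0291091241908115
74,0.0318224125419962
75,0.0347884533076828
76,0.0380298749125227
77,0.0415711473683623
78,0.0454386944026031
79,0.0496610041667757
80,0.0542687362168949
81,0.059294821885752
82,0.0647745544967032
83,0.0707456650877385
84,0.0772483784132916
85,0.0843254429605604
86,0.0920221275509444
87,0.100386175793878
88,0.109467708224724
89,0.119319060404778
90,0.129994543617017
91,0.141550113100814
92,0.15404292709973
93,0.167530778445683
94,0.182071379103357
95,0.19772147722867
96,0.214535786085485
97,0.232565704907232
98,0.251857813844229
99,0.272452128932484
100,1
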