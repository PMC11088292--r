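age,qx
0,0.000529660635661511
1,0.000532530874245429
2,0.000535677693387582
3,0.000539127743810597
4,0.000542910244042738
5,0.000547057227786141
6,0.000551603815106216
7,0.000556588509736056
8,0.000562053525007156
9,0.000568045141161266
10,0.000574614097061499
11,0.000581816019611159
12,0.000589711894505962
13,0.000598368582292341
14,0.000607859384087917
15,0.000618264661734313
16,0.00062967251761159
17,0.00064217953984369
18,0.000655891619172011
19,0.000670924844374254
20,0.000687406483763531
21,0.000705476061019672
22,0.000725286534393521
23,0.000747005589185945
24,0.00077081705434312
25,0.00079692245504237
26,0.000825542714267935
27,0.000856920017607954
28,0.000891319856849648
29,0.000929033269421509
30,0.000970379292334789
31,0.00101570765103198
32,0.00106540170546476
33,0.00111988167780619
34,0.00117960818848295
35,0.00124508612969043
36,0.00131686890825056
37,0.00139556309261657
38,0.00148183350201492
39,0.00157640877919185
40,0.00168008749199089
41,0.00179374481307615
42,0.00191833983153189
43,0.00205492355485004
44,0.00220464766497852
45,0.00236877409766301
46,0.00254868552029919
47,0.00274589678993287
48,0.00296206747992067
49,0.00319901557110247
50,0.00345873241114658
51,0.00374339905400511
52,0.00405540410015104
53,0.00439736316743644
54,0.00477214013197291
55,0.00518287028833853
56,0.00563298558857017
57,0.00612624212970281
58,0.00666675006991468
59,0.00725900616343833
60,0.00790792911405735
61,0.00861889795590254
62,0.00939779367800853
63,0.0102510443151888
64,0.011185673731629
65,0.0122093543244385
66,0.01333046387132
67,0.0145581467384162
68,0.015902379649911
69,0.0173740421985087
70,0.0189849922435292
71,0.020748146298764
72,0.0226775649526746
73,0.0247885432857916
74,0.0270977061504792
75,0.029623108052183
76,0.0323843372137448
77,0.0354026232094945
78,0.038700947316884
79,0.0423041544428479
80,0.0462390651313856
81,0.0505345857387166
82,0.0552218143626444
83,0.060334139522755
84,0.0659073278966888
85,0.0719795966140621
86,0.0785916646835098
87,0.0857867770713946
88,0.0936106937575806
89,0.102111634763726
90,0.111340170689282
91,0.121349046716301
92,0.132192926386554
93,0.14392803976206
94,0.156611718925608
95,0.170301802264583
96,0.185055887750716
97,0.200930414668037
98,0.217979553193559
99,0.236253882204804
100,1
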