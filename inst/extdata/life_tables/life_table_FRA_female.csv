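age,qx
0,0.000506309546737804
1,0.000507021914481376
2,0.000507813148297509
3,0.000508691979358211
4,0.000509668105436178
5,0.000510752297910644
6,0.000511956520616974
7,0.00051329406185352
8,0.000514779680998556
9,0.000516429771357463
10,0.00051826254103382
11,0.000520298213820158
12,0.000522559252323251
13,0.000525070605783218
14,0.000527859985320789
15,0.000530958169644324
16,0.000534399344587766
17,0.000538221480221424
18,0.000542466749690496
19,0.000547181994396517
20,0.000552419240645863
21,0.000558236273454638
22,0.000564697273829573
23,0.000571873526539646
24,0.000579844206166746
25,0.000588697250086145
26,0.000598530327975855
27,0.000609451918514803
28,0.000621582505104024
29,0.000635055903743798
30,0.000650020737646861
31,0.000666642074769963
32,0.000685103246219732
33,0.000705607865461144
34,0.000728382070439682
35,0.000753677013147547
36,0.000781771623845406
37,0.000812975680123174
38,0.00084763321426784
39,0.000886126296052336
40,0.000928879232083957
41,0.000976363227308541
42,0.00102910155919245
43,0.00108767532054721
44,0.00115272979297354
45,0.00122498151953354
46,0.00130522615257445
47,0.00139434716068698
48,0.00149332548764913
49,0.00160325026596175
50,0.00172533069828917
51,0.00186090923186433
52,0.00201147616377573
53,0.00217868582910685
54,0.00236437453922533
55,0.00257058045419689
56,0.00279956559139494
57,0.00305384019194965
58,0.00333618968777749
59,0.0036497045345667
60,0.00399781320026082
61,0.00438431862422595
62,0.00481343848929328
63,0.00528984967706569
64,0.00581873730597182
65,0.00640584878115746
66,0.00705755331486246
67,0.00778090740469339
68,0.0085837267841733
69,0.00947466538384578
70,0.0104633018603311
71,0.0115602342629705
72,0.0127771834103071
73,0.0141271055382535
74,0.0156243147541134
75,0.0172846157803914
76,0.0191254473930217
77,0.021166036842315
78,0.0234275653818526
79,0.0259333448090316
80,0.0287090046268917
81,0.0317826890534736
82,0.0351852626124367
83,0.0389505224138357
84,0.0431154144499966
85,0.0477202502577685
86,0.0528089191007234
87,0.0584290893654592
88,0.064632391104787
89,0.071474569555944
90,0.0790155969741911
91,0.0873197272163975
92,0.0964554741613401
93,0.106495491257568
94,0.117516325269002
95,0.129598012709391
96,0.142823482647694
97,0.157277724741234
98,0.173046676840462
99,0.190215782785574
100,1
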