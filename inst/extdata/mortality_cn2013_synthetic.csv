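age,male,female
20,0.00028144980950162157,0.00022516618543444444
21,0.00029853648954258905,0.00023883632240850883
22,0.00031723196085209349,0.00025379362059285704
23,0.00033768766421715668,0.00027015925524287443
24,0.00036006928924214865,0.00028806580487938938
25,0.00038455811365711856,0.0003076583235412933
26,0.00041135246824641758,0.00032909551369331158
27,0.00044066933913289308,0.00035255100920272842
28,0.00047274612022984996,0.00037821477867727715
29,0.00050784252986246781,0.00040629466040520423
30,0.00054624270684699994,0.00043701804118245757
31,0.00058825750272406552,0.00047063369244659814
32,0.00063422698837356517,0.00050741377837515422
33,0.00068452319490774904,0.00054765605195428169
34,0.00073955311055418083,0.00059168625649663742
35,0.00079976195721742638,0.00063986075168565026
36,0.00086563677255402371,0.00069256938497153087
37,0.00093771032573308766,0.00075023863103740318
38,0.0010165653975858779,0.00081333502412084258
39,0.0011028394586012347,0.0008823689102194221
40,0.0011972297812016253,0.00095789854864336554
41,0.0013004990259674054,0.0010405345950266209
42,0.0014134813449665495,0.0011309450007737087
43,0.0015370890491240852,0.0012298603670282127
44,0.0016723198906400949,0.0013380797946159761
45,0.0018202650158501976,0.0014564772750502719
46,0.0019821176486496395,0.0015860086716159572
47,0.0021591825696680722,0.0017277193437873484
48,0.0023528864618147516,0.0018827524727923484
49,0.0025647891986185778,0.0020523581510379918
50,0.0027965961579745624,0.0022379033033690376
51,0.003050171650479272,0.0024408825137548495
52,0.0033275535584965654,0.0026629298370052235
53,0.0036309692894244128,0.0029058316814994933
54,0.0039628531543220991,0.003171540855689714
55,0.0043258652910718176,0.003462191878291665
56,0.0047229122595410233,0.0037801176595951835
57,0.0051571694447228866,0.0041278676691917093
58,0.0056321054124681691,0.0045082277135803928
59,0.0061515083710781404,0.0049242414555297209
60,0.0067195149005367938,0.0053792338156647412
61,0.0073406411193509546,0.0058768364054059274
62,0.0080198164665796767,0.006421015148992959
63,0.0087624202833711529,0.0070161002606938805
64,0.0095743213838134222,0.0076668187512231034
65,0.010461920808672476,0.0083783296445929523
66,0.011432197957066847,0.0091562620927612137
67,0.012492760289628646,0.010006756580093201
68,0.013651896791369467,0.010936509412311946
69,0.014918635372303757,0.011952820684629217
70,0.016302804367657964,0.013063645920373235
71,0.017815098275759,0.014277651563717964
72,0.019467147838720278,0.01560427449696522
73,0.021271594526775961,0.017053785732893512
74,0.023242169429154358,0.018637358404376858
75,0.025393776479885055,0.020367140134898487
76,0.027742579852628291,0.022256329822512688
77,0.030306095240659636,0.024319258803620736
78,0.033103284592164384,0.026571476278555495
79,0.036154653691952476,0.029029838774861982
80,0.039482351762921253,0.03171260329220027
81,0.043110271997668592,0.034639523610268563
82,0.047064151615515581,0.037831949042681168
83,0.051371669665088548,0.041312924679289043
84,0.056062540349202328,0.045107291870239874
85,0.061168599128349044,0.049241787359709188
86,0.066723878252717306,0.053745139067632453
87,0.072764667671692096,0.058648156035350674
88,0.079329556466333662,0.063983809486998555
89,0.086459449038141178,0.069787301303869786
90,0.094197549262838409,0.076096115455553726
91,0.10258930468146954,0.082950047072198774
92,0.11168230155916625,0.090391202871773269
93,0.12152610030930699,0.098463965572966217
94,0.13217199938348245,0.10721491373172087
95,0.14367271430673167,0.11669268714773084
96,0.15608195715327589,0.12694778661679385
97,0.16945390049532805,0.13803229538904072
98,0.18384250883162856,0.14999950828224029
99,0.19930071986491782,0.16290345306605747
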