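age,male,female
20,0.0028662087949434365,0.0028662087949434365
21,0.0030901733131794289,0.0030901733131794289
22,0.0033304017787545328,0.0033304017787545328
23,0.0035878771131875671,0.0035878771131875671
24,0.0038636101068329942,0.0038636101068329942
25,0.0041586348246961191,0.0041586348246961191
26,0.004474002966678073,0.004474002966678073
27,0.0048107770855346415,0.0048107770855346415
28,0.0051700225729124786,0.0051700225729124786
29,0.0055527983355703782,0.0055527983355703782
30,0.0059601461011058784,0.0059601461011058784
31,0.0063930783159540667,0.0063930783159540667
32,0.0068525646287729836,0.0068525646287729836
33,0.0073395169900691195,0.0073395169900691195
34,0.0078547734442726367,0.0078547734442726367
35,0.0083990807433037759,0.0083990807433037759
36,0.0089730759703663416,0.0089730759703663416
37,0.0095772674280733758,0.0095772674280733758
38,0.010212015114204588,0.010212015114204588
39,0.010877511178844375,0.010877511178844375
40,0.01157376082504912,0.01157376082504912
41,0.012300564177552596,0.012300564177552596
42,0.013057499695787549,0.013057499695787549
43,0.013843909743780509,0.013843909743780509
44,0.014658888945321621,0.014658888945321621
45,0.015501275943619377,0.015501275943619377
46,0.01636964914661198,0.01636964914661198
47,0.017262326969684039,0.017262326969684039
48,0.018177372985921682,0.018177372985921682
49,0.019112606261537553,0.019112606261537553
50,0.020065616994377401,0.020065616994377401
51,0.021033787392562529,0.021033787392562529
52,0.022014317536640352,0.022014317536640352
53,0.023004255772221715,0.023004255772221715
54,0.024000532992220915,0.024000532992220915
55,0.025000000000000001,0.025000000000000001
56,0.025999467007779092,0.025999467007779092
57,0.026995744227778284,0.026995744227778284
58,0.027985682463359651,0.027985682463359651
59,0.028966212607437473,0.028966212607437473
60,0.029934383005622602,0.029934383005622602
61,0.03088739373846245,0.03088739373846245
62,0.031822627014078321,0.031822627014078321
63,0.032737673030315967,0.032737673030315967
64,0.033630350853388023,0.033630350853388023
65,0.034498724056380624,0.034498724056380624
66,0.035341111054678381,0.035341111054678381
67,0.036156090256219492,0.036156090256219492
68,0.03694250030421245,0.03694250030421245
69,0.037699435822447412,0.037699435822447412
70,0.038426239174950881,0.038426239174950881
71,0.039122488821155627,0.039122488821155627
72,0.039787984885795415,0.039787984885795415
73,0.040422732571926627,0.040422732571926627
74,0.041026924029633663,0.041026924029633663
75,0.041600919256696227,0.041600919256696227
76,0.042145226555727368,0.042145226555727368
77,0.042660483009930882,0.042660483009930882
78,0.043147435371227019,0.043147435371227019
79,0.043606921684045938,0.043606921684045938
80,0.044039853898894123,0.044039853898894123
81,0.044447201664429621,0.044447201664429621
82,0.044829977427087518,0.044829977427087518
83,0.045189222914465366,0.045189222914465366
84,0.045525997033321934,0.045525997033321934
85,0.045841365175303884,0.045841365175303884
86,0.046136389893167012,0.046136389893167012
87,0.046412122886812429,0.046412122886812429
88,0.046669598221245466,0.046669598221245466
89,0.046909826686820574,0.046909826686820574
90,0.04713379120505657,0.04713379120505657
91,0.047342443180096817,0.047342443180096817
92,0.047536699695798663,0.047536699695798663
93,0.047717441460777811,0.047717441460777811
94,0.047885511407898311,0.047885511407898311
95,0.048041713860161789,0.048041713860161789
96,0.048186814181267586,0.048186814181267586
97,0.048321538835925881,0.048321538835925881
98,0.048446575792016632,0.048446575792016632
99,0.048562575203672999,0.048562575203672999
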