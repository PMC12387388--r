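exam,mva_cm2,reported_grade
1,4.2,no_stenosis
2,5.3,no_stenosis
3,5.1,no_stenosis
4,4.0,no_stenosis
5,5.5,no_stenosis
6,4.9,no_stenosis
7,7.4,no_stenosis
8,4.5,no_stenosis
9,2.7,mild
10,1.6,mild
11,1.6,mild
12,1.8,mild
13,3.7,mild
14,2.6,mild
15,3.2,mild
16,1.6,mild
17,1.0,moderate
18,1.1,moderate
19,1.0,moderate
20,1.1,moderate
21,0.7,severe
22,0.9,severe
23,0.5,severe
24,0.4,severe
25,0.6,severe
26,0.4,severe
27,0.7,severe
28,0.6,severe
29,0.7,severe
30,0.7,severe
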