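age_start,weight
20,0.122
25,0.114
30,0.107
35,0.100
40,0.092
45,0.084
50,0.076
55,0.067
60,0.058
65,0.049
70,0.040
75,0.032
80,0.023
85,0.016
90,0.010
95,0.010
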