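"source","parameter","value"
"source_1","R_T",30000
"source_2","R_T",15708
"source_3","R_T",20000
"source_4","R_T",30000
"source_1","kappa",1e-04
"source_2","kappa",3.1831e-05
"source_3","kappa",1e-04
"source_4","kappa",1e-05
"source_1","S_T",6e+05
"source_2","S_T",6e+05
"source_3","S_T",6e+05
"source_4","S_T",3e+05
"source_1","phi",0.09
"source_2","phi",1
"source_3","phi",1
"source_4","phi",0.05
"source_1","b",0.04
"source_2","b",0.04
"source_3","b",0.04
"source_4","b",0.02
"source_1","gamma",1.2e-06
"source_3","gamma",0.00044
"source_4","gamma",0.00044
"source_1","alpha",2e-04
"source_4","alpha",1e-04
"source_1","beta",1
"source_4","beta",0.006
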