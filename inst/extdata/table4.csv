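patient,m1_mm,m2_mm,probe_mm,sentinel
1,4,4,3,FALSE
2,NA,NA,2,TRUE
3,5,4,3,FALSE
4,NA,NA,0.2,TRUE
6,NA,NA,1.2,TRUE
7,NA,NA,2,TRUE
8,NA,NA,0,TRUE
9,-5,-4,-4,FALSE
10,-4,-6,-4,FALSE
11,20,20,22,FALSE
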