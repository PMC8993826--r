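study,set,basis,total,pos,neg,tp,tn,fp,fn,acc,prec,rec,f1,spec,mcc,npv,ts,note
1,In-text,per-finding,,338,,337,,,1,,,1.00,,,,,,
2,T2.R1,per-frame,210,143,67,,,,,0.71,0.89,0.68,0.75,,,,,
2,T2.R2,per-frame,210,143,67,,,,,0.77,0.81,0.88,0.83,,,,,
2,T2.R3,per-frame,210,143,67,,,,,0.87,0.91,0.84,0.87,,,,,
2,T3.R1,per-frame,48,13,35,,,,,,0.65,0.85,0.73,,,,,
2,T3.R2,per-frame,48,35,13,,,,,,0.94,0.83,0.88,,,,,
2,T3.R3,per-frame,,,,,,,,0.83,0.86,0.83,0.84,,,,,
3,T1,per-frame,106,,,65,33,7,1,0.94,0.90,0.98,,0.83,,0.97,,
4,T2.R1,per-frame,6000,6000,0,5663,0,251,337,,,0.94,,,,,,negative class unbounded; stated neg total 0 despite fp > 0
4,T2.R2,per-frame,1414,1414,0,1296,0,41,118,,,0.92,,,,,,negative class unbounded; stated neg total 0 despite fp > 0
4,T2.R3,per-frame,21572,0,21572,0,20691,1004,0,,NA,,,0.96,,,,fp digits garbled in source; 1004 inferred from the pooled row (1255 - 251)
4,T2.R4,per-frame,,,,570,0,42,76,,,0.88,,,,,,
4,D3.In-text,per-frame,60914,,,,,,,,,0.92,,,,,,
4,D4.In-text,per-frame,1072483,0,1072483,0,,,0,,,,,0.95,,,,
5,T1,per-frame,,,,3723,4735,262,930,0.88,0.93,0.80,,0.95,,,,ppv 0.934 reported in the study text rather than its table
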