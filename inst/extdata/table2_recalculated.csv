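study,set,basis,total,pos,neg,tp,tn,fp,fn,acc,prec,rec,f1,spec,mcc,npv,ts,note
1,In-text,per-polyp,16900000,338,16899662,337,16730662,169000,1,0.99,0.00,1.00,0.00,0.99,0.04,1.00,0.00,
1,Calculated,per-frame,16900000,84500,16815500,84500,16646500,169000,250,0.99,0.33,1.00,0.50,0.99,0.57,1.00,0.33,stated pos 84500 vs tp + fn = 84750; entry sum 16900250 exceeds stated total 16900000
2,T2.R1,per-frame,210,143,67,97,55,12,46,0.71,0.89,0.68,0.77,0.82,0.47,0.55,0.63,echo:acc acc carried forward from the reported table; printed counts give 0.72
2,T2.R2,per-frame,210,143,67,116,40,27,27,0.77,0.81,0.88,0.81,0.59,0.40,0.59,0.68,echo:acc echo:rec acc and rec carried forward from the reported table; printed counts give 0.74 and 0.81
2,T2.R3,per-frame,210,143,67,130,54,13,13,0.87,0.91,0.84,0.91,0.81,0.72,0.81,0.83,echo:rec rec carried forward from the reported table; printed counts give 0.91
2,T3.R1,per-frame,48,13,35,11,29,6,2,0.84,0.65,0.85,0.74,0.83,0.63,0.94,0.58,
2,T3.R2,per-frame,48,35,13,29,11,2,6,0.84,0.94,0.83,0.88,0.86,0.64,0.65,0.79,unrounded:spec unrounded:mcc spec and mcc computed from unrounded derived counts; printed integer counts give 0.85 and 0.63
2,AVG,,,,,,,,,0.84,0.80,0.84,0.81,0.84,0.63,0.79,0.69,unweighted mean of the T3.R1 and T3.R2 rows
2,WAVG,,,,,,,,,0.84,0.86,0.84,0.84,0.85,0.64,0.73,0.73,mean of the T3.R1 and T3.R2 rows weighted by positive-class counts 13 and 35
3,T1,per-frame,106,66,40,65,33,7,1,0.92,0.90,0.98,0.94,0.83,0.84,0.97,0.89,
4,T2.R1,per-frame,6000,6000,0,5663,0,251,337,0.94,0.96,0.94,0.95,NA,-0.05,0,0.91,negative class unbounded; stated neg total 0 despite fp > 0
4,T2.R2,per-frame,1414,1414,0,1296,0,41,118,0.92,0.97,0.92,0.94,NA,-0.05,0,0.89,negative class unbounded; stated neg total 0 despite fp > 0
4,T2.R3,per-frame,21572,0,21695,0,20691,1004,0,0.95,0,NA,0,0.95,NA,1,0,fp digits garbled in source; 1004 inferred from the pooled row (1255 - 251)
4,Combined,per-frame,27572,6000,21695,5663,20691,1255,337,0.95,0.82,0.94,0.88,0.95,0.84,0.98,0.78,stated total 27572 vs pos + neg = 27695
4,Biased POS,per-frame,27572,6000,21695,6000,0,21695,0,0.22,0.22,1,0.36,0,NA,NA,0.22,stated total 27572 vs pos + neg = 27695
4,Biased NEG,per-frame,27572,6000,21695,0,21695,0,6000,0.78,NA,0,0,1,NA,0.78,0,stated total 27572 vs pos + neg = 27695
4,T2.R4,per-frame,646,646,42,570,0,42,76,0.83,0.93,0.88,0.91,0,-0.09,0,0.83,stated total 646 vs pos + neg = 688
4,D3.In-text,per-frame,60914,,,,,,,,,0.92,,,,,,
4,D4.In-text,per-frame,1072483,0,1072483,0,1023149,49334,0,0.95,0,NA,0,0.95,NA,1,0,
5,T1,per-frame,9650,4653,4997,3723,4735,262,930,0.88,0.93,0.80,0.86,0.95,0.76,0.84,0.76,
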