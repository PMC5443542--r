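term,group,estimate,se
(Intercept),Inuit,1262,423
RNFB,Inuit,0.625,0.239
RNFB_dist,Inuit,0.035,0.017
ICCPI,Inuit,-10.89,4.01
ICCPI_dist,Inuit,0.024,0.018
Pop,Inuit,-0.007,0.004
adj_r_squared,Inuit,0.49,NA
f_statistic,Inuit,9.13,NA
(Intercept),FirstNations,1606,413
ICCPI,FirstNations,-12.86,4.05
ICCPI_dist,FirstNations,0.048,0.011
Pop,FirstNations,-0.006,0.004
adj_r_squared,FirstNations,0.42,NA
f_statistic,FirstNations,11.51,NA
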