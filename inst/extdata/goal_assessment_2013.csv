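goal_id,goal_name,subgoal_id,subgoal_name,score,status,future,trend,pressure,resilience
FP,Food Provision,NA,NA,64.28,58.66,69.90,0.02,NA,NA
FP,Food Provision,FIS,Wild Caught Fisheries,59.36,54.00,64.72,0.02,16.69,72.81
FP,Food Provision,MAR,Mariculture,92.88,85.77,100.00,0.04,14.01,68.68
AN,Aboriginal Needs,NA,NA,35.42,32.39,38.45,-0.02,13.58,73.66
NP,Natural Products,NA,NA,44.02,41.90,46.13,-0.16,13.81,76.43
CS,Carbon Storage,NA,NA,61.64,57.28,66.00,-0.01,16.52,64.06
CP,Coastal Protection,NA,NA,95.89,91.79,100.00,-0.01,23.81,64.06
CL,Coastal Livelihoods,NA,NA,89.87,86.74,93.00,0.03,NA,NA
CL,Coastal Livelihoods,LIV,Livelihoods,79.74,73.48,86.00,0.03,14.89,60.08
CL,Coastal Livelihoods,ECO,Economies,100.00,100.00,100.00,0.02,14.87,73.55
TR,Tourism & Recreation,NA,NA,25.19,23.93,26.45,0.00,30.64,62.97
SP,Sense of Place,NA,NA,59.40,52.63,66.17,0.34,NA,NA
SP,Sense of Place,ICO,Iconic Species,84.91,80.00,89.81,-0.10,16.99,74.46
SP,Sense of Place,LSP,Lasting Special Places,33.89,25.27,42.52,0.78,22.84,72.06
CW,Clean Waters,NA,NA,78.70,84.31,73.09,-0.32,38.19,62.97
BD,Biodiversity,NA,NA,91.05,84.83,97.28,-0.04,NA,NA
BD,Biodiversity,HAB,Habitats,92.72,85.43,100.00,0.00,14.73,75.38
BD,Biodiversity,SPP,Species,89.39,84.22,94.55,-0.08,19.67,72.83
OHI,Overall Index,NA,NA,64.55,NA,67.65,NA,NA,NA
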