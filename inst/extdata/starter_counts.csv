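target,animal_id,total_inputs,pulvinar,LD,POm,dLGN,CL,pulvinar_printed_pct
PM,PM1,8104,141,4,2,2,4,92.2
PM,PM2,4658,403,45,1,20,1,85.2
PM,PM3,2960,835,122,0,10,7,85.2
PM,PM4,1720,666,224,5,2,8,73.4
PM,PM5,4612,377,74,19,5,26,73.8
AM,AM1,1548,313,203,0,11,0,59.3
AM,AM2,5179,337,32,2,6,8,87.1
AM,AM3,1707,292,5,17,2,0,92.4
AM,AM4,2584,158,44,58,4,14,55.4
AM,AM5,1955,200,15,10,4,0,86.6
RL,RL1,5777,527,150,12,14,6,74.3
RL,RL2,9474,1058,148,19,2,4,86.0
RL,RL3,989,300,40,0,5,2,86.2
RL,RL4,2401,339,70,39,3,5,73.9
AL,AL1,9015,1315,82,6,27,8,91.1
AL,AL2,2991,819,24,1,1,41,92.3
AL,AL3,3124,678,36,39,52,1,83.3
AL,AL4,2139,155,5,56,3,0,68.3
AL,AL5,3692,368,0,16,8,0,92.7
LM,LM1,2627,117,0,0,3,1,95.9
LM,LM2,1743,85,0,0,0,0,100
LM,LM3,2562,88,10,2,9,4,75.2
LM,LM4,2732,544,56,12,28,30,81.1
LM,LM5,3280,638,100,0,78,1,77.9
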