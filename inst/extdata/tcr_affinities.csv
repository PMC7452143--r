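group,label,pdb,type,kd_nM,on_rate,off_rate
1G4-A2-SLL,1G4,2BNR,wild-type,13300,12000,0.049
1G4-A2-SLL,1G4_c5c1,2PYE,variant,81.6,17800,0.0015
1G4-A2-SLL,1G4_c49c50,2F53,variant,1,180000,0.00024
1G4-A2-SLL,1G4_c58c61,2P5E,variant,0.048,570000,0.00003
1G4-A2-SLL,1G4_c58c62,2P5W,variant,NA,NA,0.00003
DMF5-A2-ELA,DMF5,3QDG,wild-type,29000,NA,NA
DMF5-A2-ELA,DMF5_YW,4L3E,variant,24,NA,NA
MEL5-A2-ELA,MEL5,3HG1,wild-type,18000,NA,NA
MEL5-A2-ELA,MEL5_a24b17,4JFF,variant,0.61,79000,0.0001
MEL5-A2-EAA,MEL5,4QOK,wild-type,8400,NA,NA
MEL5-A2-EAA,MEL5_a24b17,6TMO,variant,0.75,280000,0.00021
MEL5-A2-AAG,MEL5,6EQA,wild-type,14200,NA,NA
MEL5-A2-AAG,MEL5_a24b17,6EQB,variant,26.2,74000,0.0019
A6-A2-LLF,A6,1AO7,wild-type,3200,23000,0.074
A6-A2-LLF,A6_c134,4FTV,variant,4,45000,0.00018
ILA1-A2-ILA,ILA1,5MEN,wild-type,34000,3490,0.13
ILA1-A2-ILA,ILA1_a1b1,4MNQ,variant,2,80000,0.00016
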