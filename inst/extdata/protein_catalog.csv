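name,species,mw_da,catabolic_organ,T_M_min,T_P1_min,T_P2_min,T_T1_min,T_T2_min,Cl_p_ml_min,f1,f2,L1_ml_min,L2_ml_min,liver_recycled
albumin,human,66500,endothelium,16750,4385,1929,4182,557,0.167,0.734,0.722,0.87,2.00,FALSE
mepolizumab,human,149000,endothelium,21202,8770,3859,4182,557,0.132,0.367,0.361,0.87,2.00,FALSE
infliximab,human,149000,endothelium,11964,8770,3895,4182,557,0.23,0.367,0.361,0.87,2.00,FALSE
recAP,human,140000,liver,1100,8770,3859,4182,557,66.2,0.367,0.361,0.87,2.00,TRUE
placental_ALP,human,140000,liver,7537,8770,3859,4182,557,0.371,0.367,0.361,0.87,2.00,FALSE
amylase,baboon,57086,kidney,100,4385,1929,4182,557,27.9,0.734,0.722,0.87,2.00,FALSE
lipase,baboon,48000,kidney,100,4385,1929,4182,557,27.9,0.734,0.722,0.87,2.00,FALSE
ALT,dog,54600,sinusoidal,2949,4385,1929,2323,310,0.949,0.530,0.535,1.2,2.71,FALSE
AST_mitochondrial,dog,47517,kupffer,49.1,4385,1929,2323,310,56.9,0.530,0.535,1.2,2.71,FALSE
AST_cytoplasmic,dog,46247,sinusoidal,689,4385,1929,2323,310,4.06,0.530,0.535,1.2,2.71,FALSE
creatine_kinase,dog,81000,kupffer,88.1,6265,2756,2323,310,31.7,0.370,0.374,1.2,2.71,FALSE
LD1,lamb,138000,sinusoidal,2871,1370,3859,726,619,0.975,0.53,0.53,3.85,1.35,FALSE
LD5,lamb,138000,kupffer,440,1370,3859,726,619,6.35,0.53,0.53,3.85,1.35,FALSE
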