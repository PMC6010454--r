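id,group,score,pre,post,followup
BCI01,bci,FMA-UE,11,21,21
BCI01,bci,MAS-flexor,2,2,2
BCI01,bci,MAS-extensor,1,0,1
BCI01,bci,MRC,1,1,2
BCI01,bci,ESS,61,62,NA
BCI02,bci,FMA-UE,35,44,45
BCI02,bci,MAS-flexor,1,1,1
BCI02,bci,MAS-extensor,1,1,0
BCI02,bci,MRC,2,4,4
BCI02,bci,ESS,79,100,NA
BCI03,bci,FMA-UE,37,55,44
BCI03,bci,MAS-flexor,2,2,3
BCI03,bci,MAS-extensor,0,0,0
BCI03,bci,MRC,2,4,3
BCI03,bci,ESS,84,84,NA
BCI04,bci,FMA-UE,35,44,35
BCI04,bci,MAS-flexor,2,2,2
BCI04,bci,MAS-extensor,1,1,1
BCI04,bci,MRC,3,3,4
BCI04,bci,ESS,79,79,NA
BCI05,bci,FMA-UE,7,14,NA
BCI05,bci,MAS-flexor,4,3,NA
BCI05,bci,MAS-extensor,4,3,NA
BCI05,bci,MRC,0,3,NA
BCI05,bci,ESS,49,55,NA
BCI06,bci,FMA-UE,23,31,28
BCI06,bci,MAS-flexor,2,2,3
BCI06,bci,MAS-extensor,0,0,0
BCI06,bci,MRC,2,3,3
BCI06,bci,ESS,70,72,70
BCI07,bci,FMA-UE,24,28,31
BCI07,bci,MAS-flexor,0,1,2
BCI07,bci,MAS-extensor,3,3,3
BCI07,bci,MRC,1,2,3
BCI07,bci,ESS,76,78,78
BCI08,bci,FMA-UE,35,47,48
BCI08,bci,MAS-flexor,0,1,0
BCI08,bci,MAS-extensor,0,0,0
BCI08,bci,MRC,1,4,4
BCI08,bci,ESS,77,81,85
BCI09,bci,FMA-UE,11,11,14
BCI09,bci,MAS-flexor,2,3,2
BCI09,bci,MAS-extensor,1,1,2
BCI09,bci,MRC,0,2,2
BCI09,bci,ESS,39,41,41
BCI10,bci,FMA-UE,14,26,26
BCI10,bci,MAS-flexor,1,1,3
BCI10,bci,MAS-extensor,0,0,0
BCI10,bci,MRC,2,3,2
BCI10,bci,ESS,57,62,62
BCI11,bci,FMA-UE,22,22,23
BCI11,bci,MAS-flexor,3,3,3
BCI11,bci,MAS-extensor,2,1,0
BCI11,bci,MRC,2,3,3
BCI11,bci,ESS,65,65,65
BCI12,bci,FMA-UE,8,8,8
BCI12,bci,MAS-flexor,2,3,3
BCI12,bci,MAS-extensor,2,2,3
BCI12,bci,MRC,2,2,2
BCI12,bci,ESS,63,63,63
BCI13,bci,FMA-UE,16,16,18
BCI13,bci,MAS-flexor,0,0,1
BCI13,bci,MAS-extensor,0,0,0
BCI13,bci,MRC,0,0,1
BCI13,bci,ESS,61,62,62
BCI14,bci,FMA-UE,25,29,29
BCI14,bci,MAS-flexor,2,2,2
BCI14,bci,MAS-extensor,1,1,0
BCI14,bci,MRC,2,2,2
BCI14,bci,ESS,67,70,70
sham01,sham,FMA-UE,23,31,26
sham01,sham,MAS-flexor,3,2,NA
sham01,sham,MAS-extensor,3,1,NA
sham01,sham,MRC,1,1,NA
sham01,sham,ESS,68,73,NA
sham02,sham,FMA-UE,4,8,10
sham02,sham,MAS-flexor,3,2,2
sham02,sham,MAS-extensor,3,1,1
sham02,sham,MRC,0,1,1
sham02,sham,ESS,38,41,41
sham03,sham,FMA-UE,5,4,5
sham03,sham,MAS-flexor,4,3,NA
sham03,sham,MAS-extensor,4,2,NA
sham03,sham,MRC,0,0,NA
sham03,sham,ESS,50,50,NA
sham04,sham,FMA-UE,25,24,30
sham04,sham,MAS-flexor,3,1,3
sham04,sham,MAS-extensor,2,1,1
sham04,sham,MRC,1,1,1
sham04,sham,ESS,70,70,70
sham05,sham,FMA-UE,11,11,11
sham05,sham,MAS-flexor,0,0,0
sham05,sham,MAS-extensor,0,0,0
sham05,sham,MRC,2,3,3
sham05,sham,ESS,64,64,64
sham06,sham,FMA-UE,8,8,8
sham06,sham,MAS-flexor,3,3,1
sham06,sham,MAS-extensor,0,0,0
sham06,sham,MRC,0,0,0
sham06,sham,ESS,61,61,61
sham07,sham,FMA-UE,19,21,22
sham07,sham,MAS-flexor,3,2,3
sham07,sham,MAS-extensor,1,0,1
sham07,sham,MRC,2,2,2
sham07,sham,ESS,70,72,72
sham08,sham,FMA-UE,25,32,37
sham08,sham,MAS-flexor,1,2,3
sham08,sham,MAS-extensor,1,1,0
sham08,sham,MRC,2,3,3
sham08,sham,ESS,77,77,77
sham09,sham,FMA-UE,22,26,31
sham09,sham,MAS-flexor,3,3,3
sham09,sham,MAS-extensor,1,1,1
sham09,sham,MRC,2,2,3
sham09,sham,ESS,68,68,68
sham10,sham,FMA-UE,40,43,45
sham10,sham,MAS-flexor,1,1,2
sham10,sham,MAS-extensor,0,1,0
sham10,sham,MRC,3,3,3
sham10,sham,ESS,79,79,77
sham11,sham,FMA-UE,31,32,NA
sham11,sham,MAS-flexor,0,0,NA
sham11,sham,MAS-extensor,0,0,NA
sham11,sham,MRC,2,3,NA
sham11,sham,ESS,57,57,NA
sham12,sham,FMA-UE,13,13,13
sham12,sham,MAS-flexor,3,3,3
sham12,sham,MAS-extensor,0,0,0
sham12,sham,MRC,0,0,0
sham12,sham,ESS,58,58,58
sham13,sham,FMA-UE,33,33,34
sham13,sham,MAS-flexor,0,0,0
sham13,sham,MAS-extensor,0,0,1
sham13,sham,MRC,2,2,2
sham13,sham,ESS,70,70,74
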