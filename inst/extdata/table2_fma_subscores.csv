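group,section,timepoint,mean,sd,min,max
bci,wrist,pre,1.3,1.3,0,4
bci,wrist,post,3.2,3.1,0,8
bci,wrist,followup,2.5,2.6,0,8
sham,wrist,pre,2.0,2.7,0,7
sham,wrist,post,2.6,3.3,0,9
sham,wrist,followup,2.4,3.0,0,9
bci,hand,pre,2.9,3.1,0,11
bci,hand,post,4.7,4.1,0,12
bci,hand,followup,4.3,4.3,0,13
sham,hand,pre,3.4,3.0,0,8
sham,hand,post,3.7,3.0,0,8
sham,hand,followup,4.8,4.0,0,10
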