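metric,bci_mean,bci_sd,sham_mean,sham_sd,p_group,r_dfma,p_r
TP,72.36,10.53,42.30,11.52,<1e-06,0.38,0.051
TN,12.52,7.31,12.16,6.93,0.89,0.11,0.60
FP,0.00,0.00,21.50,11.33,<1e-06,-0.29,0.15
FN,14.00,8.43,24.05,6.70,0.002,-0.50,0.009
TPR,83.76,9.78,63.79,1.01,<1e-06,0.51,0.007
TNR,100.00,0.00,34.83,5.50,<1e-24,0.47,0.014
PPV,100.00,0.00,66.26,17.88,<1e-06,0.29,0.148
NPV,49.85,23.75,33.46,18.81,0.059,0.47,0.013
Accuracy,85.95,8.40,54.46,4.85,<1e-10,0.48,0.012
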