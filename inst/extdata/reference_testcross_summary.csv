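trait,tester,min,max,mean
grain_yield,T1,3994.73,7906.10,6087.90
grain_yield,T2,4206.17,7618.21,6293.15
dyanth,T1,55.13,59.81,57.49
dyanth,T2,54.19,58.47,56.45
dysk,T1,56.38,61.31,59.05
dysk,T2,55.63,60.00,58.05
pht,T1,177.69,213.81,194.32
pht,T2,165.31,213.44,188.29
eht,T1,80.31,113.88,95.26
eht,T2,77.81,107.25,90.63
pasp,T1,1.88,3.17,2.50
pasp,T2,1.96,3.25,2.57
easp,T1,1.81,3.34,2.59
easp,T2,1.91,3.00,2.50
lutein,T1,4.32,19.46,8.53
lutein,T2,4.31,14.92,7.31
zeaxanthin,T1,1.78,12.70,7.30
zeaxanthin,T2,6.05,17.71,11.95
beta_cryptoxanthin,T1,1.36,5.84,3.32
beta_cryptoxanthin,T2,2.45,6.90,4.59
alpha_carotene,T1,0.51,1.23,0.79
alpha_carotene,T2,0.53,1.48,0.89
beta_carotene,T1,6.41,16.84,10.69
beta_carotene,T2,4.16,12.40,7.49
pva,T1,8.43,18.42,12.74
pva,T2,6.20,15.07,10.23
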