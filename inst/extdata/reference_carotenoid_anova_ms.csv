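source,df,lutein,zeaxanthin,beta_cryptoxanthin,alpha_carotene,beta_carotene,pva
Env,3,722.67,385.65,12.51,2.57,829.52,909.02
Rep(Env),4,77.73,93.37,9.3,1.05,34.71,57.67
Block(Env x Rep),240,4.64,5.88,0.4,0.08,2.48,3.04
Hybrid,123,28.6,61.85,8.35,0.18,34.27,25.83
Testcross,119,29.25,60.92,11.31,2.25,34.16,25.14
Line,59,75.13,85.35,15.26,0.34,50.32,45.35
Tester,1,367.23,5215.77,388.35,2.58,2438.68,1498.54
Line x Tester,59,15.11,10.11,1.63,0.1,6.22,5.94
Hybrid x Env,369,3.45,3.31,0.37,0.06,3.15,3.25
Line x Env,177,4.41,5.22,0.53,0.09,4.97,5.17
Tester x Env,3,66.89,42.52,7.39,0.73,67.63,85.09
Line x Tester x Env,177,4.71,4.54,0.47,0.07,3.07,3.48
Error,252,2.11,764.68,0.29,0.04,1.29,1.36
Repeatability,,0.89,0.94,0.95,0.65,0.91,0.87
CV (%),,18.41,17.94,13.59,24.42,12.63,10.25
Baker ratio,,0.98,0.99,0.99,0.98,0.99,0.99
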