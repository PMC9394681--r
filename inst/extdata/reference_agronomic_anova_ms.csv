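source,df,grain_yield,dyanth,dysk,pht,eht,pasp,easp
Env,7,711565530,4052.42,3470.24,95126.36,8507.51,5.58,15.28
Rep(Env),8,17729670,13.01,14.32,888.45,626.08,0.34,0.82
Block(Env x Rep),480,1112531,2.09,2.4,163.36,123.04,0.22,0.16
Hybrid,123,7278902,15.2,16.11,1298.19,748.63,0.75,1
Testcross,119,7221635,14.72,15.50,1226.83,731.19,0.77,0.97
Line,59,10025419,29.98,32.14,2948.56,1664.49,1.14,1.29
Tester,1,21472764,504.27,470.06,17708.19,10343.3,1.46,3.58
Line x Tester,59,9365602,8.4,9.69,430.96,247.19,0.69,1.16
Hybrid x Env,860,1592711,1.75,1.9,146.29,94.81,0.23,0.19
Line x Env,177,1961929,2.35,2.52,211.3,137.75,0.27,0.23
Tester x Env,3,19595613,6.32,7.49,4137.21,673.71,1.17,0.35
Line x Tester x Env,177,1314650,1.63,1.86,176.34,85.6,0.27,0.16
Error,503,1136506,1.43,1.57,97.92,70.25,0.18,0.16
Repeatability,,0.82,0.92,0.92,0.91,0.91,0.72,0.84
CV (%),,17.19,2.1,2.14,5.16,9,17.09,15.76
Baker ratio,,0.87,0.99,0.99,0.99,0.99,0.88,0.89
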