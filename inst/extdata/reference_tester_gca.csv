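trait,t1_gca,t1_sig,t2_gca,t2_sig
grain_yield,-107.71,,108.28,
dyanth,0.51,**,-0.52,**
dysk,0.5,**,-0.5,**
pht,2.99,,-3,
eht,2.3,*,-2.3,*
pasp,-0.03,,0.03,
easp,0.04,,-0.04,
lutein,0.62,*,-0.62,*
zeaxanthin,-2.33,**,2.33,**
beta_cryptoxanthin,-0.64,**,0.64,**
alpha_carotene,-0.05,,0.05,
beta_carotene,1.59,**,-1.59,**
pva,1.25,**,-1.25,**
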