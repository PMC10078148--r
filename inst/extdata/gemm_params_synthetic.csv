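outcome,age,theta,theta_se,alpha,mu_w,nu_w
ncd_lri,25-44,0.1430,0.01807,1.6,15.5,36.8
ncd_lri,45-64,0.1430,0.01807,1.6,15.5,36.8
ncd_lri,65-79,0.1430,0.01807,1.6,15.5,36.8
ncd_lri,80+,0.1430,0.01807,1.6,15.5,36.8
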