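# Quadratic-programming estimates of Gao et al., decline phase.
# Simplified kinetics phi_i = phi_i* X (see params_gao_exp.yaml).
phi1: -0.0033
phi2: 0.0058
phi3: -0.0014
phi4: 0.0057
phi5: 0.0056
phi6: 0.0029
phi7: 0.0573
phi8: 0.0077
phi9: 0.0113
KS1_1: 0.01
KS1_2: 0.01
KS1_3: 0.01
KS3_2: 0.001
KS3_3: 0.001
KS3_4: 0.001
KS2_6: 0.01
KS2_7: 0.01
KS2_8: 0.01
KS2_9: 0.01
KS4_5: 0.001
KS5_6: 0.001
mu: 0.0399
kd: 0.06
kinetics_mode: simplified
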