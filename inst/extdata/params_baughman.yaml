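# Interior-point estimates of Baughman et al. (saturable kinetics).
phi1: 8.85e-4
phi2: 1.12e+6
phi3: 1.1e+5
phi4: 1.97e-2
phi5: 4.95
phi6: 1.34e+5
phi7: 1.36e+3
phi8: 1.0e-5
phi9: 1.83e+4
KS1_1: 1.63e+5
KS1_2: 1.08e+4
KS1_3: 1.44e+4
KS3_2: 9.64e+2
KS3_3: 1.04e+3
KS3_4: 5.42e-2
KS2_6: 3.03e+3
KS2_7: 6.39e+3
KS2_8: 3.73e-1
KS2_9: 3.23e+5
KS4_5: 7.42e+3
KS5_6: 4.45e+3
mu: 3.22e-2
kd: 4.99e-2
kinetics_mode: saturable
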