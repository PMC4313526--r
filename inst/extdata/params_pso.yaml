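# Multistep-PSO kinetic parameter estimates (saturable kinetics).
# phi*: pmol/(cell h); KS: mM; mu: 1/h; kd: per (1e6 cells/mL) per h.
phi1: 8.443e-4
phi2: 2.481e+6
phi3: 3.968e+5
phi4: 1.090e+2
phi5: 7.283
phi6: 3.337e+5
phi7: 3.977e+3
phi8: 6.697e-6
phi9: 3.261e+4
KS1_1: 8.989e+5
KS1_2: 6.495e+4
KS1_3: 3.723e+4
KS3_2: 7.076e+2
KS3_3: 2.782e+3
KS3_4: 0.019
KS2_6: 2.719e+4
KS2_7: 9.324e+3
KS2_8: 0.537
KS2_9: 6.683e+5
KS4_5: 1.920e+3
KS5_6: 4.488e+4
mu: 0.043
kd: 0.067
kinetics_mode: saturable
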