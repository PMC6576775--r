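species,psi,psi_se,theta,theta_se,p1,p1_se,p2,p2_se,p3,p3_se,p4,p4_se,p5,p5_se
Canis latrans,0.67,0.17,0.07,0.02,0.13,0.07,0.51,0.09,0.65,0.08,0.34,0.09,0.62,0.09
Pekania pennanti,0.73,0.07,0.12,0.08,0.60,0.16,0.79,0.11,0.83,0.09,0.71,0.14,0.73,0.13
Martes americana,0.76,0.08,0.24,0.02,0.29,0.07,0.47,0.06,0.79,0.06,0.55,0.07,0.58,0.07
Mustela erminea,0.51,0.12,0.33,0.04,0.24,0.05,0.47,0.06,0.60,0.06,0.52,0.06,0.77,0.05
Lepus americanus,0.50,0.12,0.36,0.03,0.37,0.07,0.49,0.08,0.72,0.06,0.49,0.07,0.61,0.07
Tamiasciurus hudsonicus,0.53,0.31,0.19,0.10,0.34,0.10,0.66,0.09,0.81,0.06,0.57,0.09,0.69,0.09
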