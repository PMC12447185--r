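recipe,mu_a_cm,mu_s_prime_cm,A_um,phi
C01AX,2.35,0.06,355,0.286
C02XD,0.09,6.94,198,0.259
C03AD,5.78,6.21,47,0.475
C04AD,3.66,1.89,128,0.396
C05AD,2.83,8.08,79,0.404
C06AD,2.05,3.64,152,0.401
C07AX,2.08,0.02,48,0.663
C08XD,0.18,3.74,825,0.166
C09AD,8.15,47.61,1,0.880
C10AD,7.04,78.13,1,0.864
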