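recipe,thickness_index,thickness_um,mu_a_cm,mu_s_prime_cm
C01AX,2,370,2.35,0.06
C01AX,3,810,2.35,0.06
C01AX,4,1190,2.35,0.06
C01AX,5,1700,2.35,0.06
C01AX,6,2120,2.35,0.06
C01AX,7,2640,2.35,0.06
C02XD,2,430,0.09,6.94
C02XD,3,600,0.09,6.94
C02XD,4,1070,0.09,6.94
C02XD,5,1650,0.09,6.94
C02XD,6,2030,0.09,6.94
C02XD,7,2500,0.09,6.94
C03AD,2,450,5.78,6.21
C03AD,3,840,5.78,6.21
C03AD,4,990,5.78,6.21
C03AD,5,1840,5.78,6.21
C03AD,6,2320,5.78,6.21
C03AD,7,2780,5.78,6.21
C04AD,2,720,3.66,1.89
C04AD,3,910,3.66,1.89
C04AD,4,1510,3.66,1.89
C04AD,5,1900,3.66,1.89
C04AD,6,2360,3.66,1.89
C04AD,7,3060,3.66,1.89
C05AD,2,550,2.83,8.08
C05AD,3,920,2.83,8.08
C05AD,4,1220,2.83,8.08
C05AD,5,1580,2.83,8.08
C05AD,6,2290,2.83,8.08
C05AD,7,2710,2.83,8.08
C06AD,2,530,2.05,3.64
C06AD,3,930,2.05,3.64
C06AD,4,1360,2.05,3.64
C06AD,5,1800,2.05,3.64
C06AD,6,2290,2.05,3.64
C06AD,7,2600,2.05,3.64
C07AX,2,430,2.08,0.02
C07AX,3,950,2.08,0.02
C07AX,4,1790,2.08,0.02
C07AX,5,2170,2.08,0.02
C07AX,6,2700,2.08,0.02
C07AX,7,3170,2.08,0.02
C08XD,2,650,0.18,3.74
C08XD,3,970,0.18,3.74
C08XD,4,1640,0.18,3.74
C08XD,5,1980,0.18,3.74
C08XD,6,2470,0.18,3.74
C08XD,7,2810,0.18,3.74
C09AD,2,490,8.15,47.61
C09AD,3,800,8.15,47.61
C09AD,4,1190,8.15,47.61
C09AD,5,1560,8.15,47.61
C09AD,6,1900,8.15,47.61
C09AD,7,2480,8.15,47.61
C10AD,2,480,7.04,78.13
C10AD,3,760,7.04,78.13
C10AD,4,1090,7.04,78.13
C10AD,5,1620,7.04,78.13
C10AD,6,1990,7.04,78.13
C10AD,7,2410,7.04,78.13
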