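# Synthetic idealized fiber nucleotide templates, form B (deoxy).
# Constructed geometry (data-raw/make_templates.py); not experimental coordinates.
# twist 36.0 rise 3.38
resname atom element x y z
DA N9 N -4.5262 -0.9032 0.0000
DA C8 C -4.8878 0.4098 0.0000
DA N7 N -3.8267 1.1630 0.0000
DA C5 C -2.7192 0.3829 0.0000
DA C6 C -1.3363 0.6292 0.0000
DA N1 N -0.5077 -0.4099 0.0000
DA C2 C -0.9646 -1.6475 0.0000
DA N3 N -2.2505 -1.9268 0.0000
DA C4 C -3.1554 -0.9530 0.0000
DA N6 N -0.8478 1.9241 0.0000
DA O4' O -6.1552 -2.1139 -1.2411
DA C4' C -7.5545 -2.5307 -0.9685
DA C2' C -6.4719 -1.8955 1.0816
DA C3' C -7.6332 -2.7332 0.5706
DA O3' O -7.4516 -4.1090 0.9109
DA C5' C -8.5301 -1.4375 -1.4081
DA O5' O -8.4087 -0.3118 -0.5377
DA P P -9.3319 0.8543 -1.1528
DA OP1 O -10.7354 0.3899 -1.2177
DA OP2 O -8.8184 1.2215 -2.6335
DA C1' C -5.4351 -2.0529 0.0000
DG N9 N -4.5262 -0.9032 0.0000
DG C8 C -4.8893 0.4115 0.0000
DG N7 N -3.8267 1.1633 0.0000
DG C5 C -2.7220 0.3779 0.0000
DG C6 C -1.3309 0.6342 0.0000
DG N1 N -0.4851 -0.4189 0.0000
DG C2 C -0.9701 -1.6917 0.0000
DG N3 N -2.2599 -1.9429 0.0000
DG C4 C -3.1589 -0.9521 0.0000
DG O6 O -0.9068 1.7769 0.0000
DG N2 N -0.0869 -2.7414 0.0000
DG O4' O -6.1543 -2.1126 -1.2411
DG C4' C -7.5535 -2.5295 -0.9685
DG C2' C -6.4709 -1.8942 1.0816
DG C3' C -7.6322 -2.7320 0.5706
DG O3' O -7.4506 -4.1078 0.9109
DG C5' C -8.5291 -1.4362 -1.4081
DG O5' O -8.4078 -0.3106 -0.5377
DG P P -9.3309 0.8556 -1.1528
DG OP1 O -10.7344 0.3912 -1.2177
DG OP2 O -8.8174 1.2227 -2.6335
DG C1' C -5.4341 -2.0516 0.0000
DC N1 N -4.5262 -0.9032 0.0000
DC C2 C -3.1966 -1.1021 0.0000
DC N3 N -2.3479 -0.0754 0.0000
DC C4 C -2.7946 1.1730 0.0000
DC C5 C -4.1834 1.4148 0.0000
DC C6 C -5.0330 0.3614 0.0000
DC O2 O -2.7601 -2.2415 0.0000
DC N4 N -1.9091 2.2258 0.0000
DC O4' O -6.1547 -2.1132 -1.2411
DC C4' C -7.5539 -2.5300 -0.9685
DC C2' C -6.4714 -1.8948 1.0816
DC C3' C -7.6326 -2.7325 0.5706
DC O3' O -7.4510 -4.1083 0.9109
DC C5' C -8.5295 -1.4368 -1.4081
DC O5' O -8.4082 -0.3111 -0.5377
DC P P -9.3313 0.8550 -1.1528
DC OP1 O -10.7348 0.3906 -1.2177
DC OP2 O -8.8179 1.2222 -2.6335
DC C1' C -5.4345 -2.0522 0.0000
DT N1 N -4.5262 -0.9032 0.0000
DT C2 C -3.1256 -1.0774 0.0000
DT N3 N -2.3815 0.1070 0.0000
DT C4 C -2.8757 1.4026 0.0000
DT C5 C -4.3594 1.5054 0.0000
DT C6 C -5.0748 0.3729 0.0000
DT O2 O -2.5713 -2.1781 0.0000
DT O4 O -2.1624 2.4020 0.0000
DT C7 C -4.9702 2.8699 0.0000
DT O4' O -6.1358 -2.0892 -1.2411
DT C4' C -7.5350 -2.5061 -0.9685
DT C2' C -6.4524 -1.8708 1.0816
DT C3' C -7.6137 -2.7086 0.5706
DT O3' O -7.4321 -4.0844 0.9109
DT C5' C -8.5106 -1.4128 -1.4081
DT O5' O -8.3892 -0.2871 -0.5377
DT P P -9.3124 0.8790 -1.1528
DT OP1 O -10.7159 0.4146 -1.2177
DT OP2 O -8.7989 1.2462 -2.6335
DT C1' C -5.4156 -2.0282 0.0000
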