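# Synthetic Hoogsteen pair template DG(syn)-DG, form B sugars.
# Constructed geometry (data-raw/make_templates.py); not experimental coordinates.
chain resno resname atom element x y z
A 1 DG N9 N -3.6322 -0.2146 0.0000
A 1 DG C8 C -2.5417 -1.0338 0.0000
A 1 DG N7 N -1.4531 -0.3202 0.0000
A 1 DG C5 C -1.7795 0.9953 0.0000
A 1 DG C6 C -1.0318 2.1960 0.0000
A 1 DG N1 N -1.7021 3.3686 0.0000
A 1 DG C2 C -3.0640 3.3833 0.0000
A 1 DG N3 N -3.7701 2.2750 0.0000
A 1 DG C4 C -3.1772 1.0757 0.0000
A 1 DG O6 O 0.1869 2.1723 0.0000
A 1 DG N2 N -3.7175 4.5895 0.0000
A 1 DG O4' O -5.7020 -0.1372 -1.1677
A 1 DG C4' C -7.0774 0.2818 -0.7951
A 1 DG C2' C -5.7546 -0.0502 1.1844
A 1 DG C3' C -7.2034 -0.0183 0.7248
A 1 DG O3' O -7.8300 -1.2840 0.9414
A 1 DG C5' C -7.2665 1.7772 -1.0558
A 1 DG C1' C -5.0333 -0.6390 0.0000
B 1 DG N9 N 4.3490 -1.3069 -0.0000
B 1 DG C8 C 4.7765 -0.0117 -0.0000
B 1 DG N7 N 3.7523 0.7916 -0.0000
B 1 DG C5 C 2.6103 0.0618 -0.0000
B 1 DG C6 C 1.2335 0.3864 -0.0000
B 1 DG N1 N 0.3368 -0.6237 -0.0000
B 1 DG C2 C 0.7583 -1.9188 -0.0000
B 1 DG N3 N 2.0341 -2.2334 -0.0000
B 1 DG C4 C 2.9809 -1.2882 -0.0000
B 1 DG O6 O 0.8663 1.5486 -0.0000
B 1 DG N2 N -0.1756 -2.9237 -0.0000
B 1 DG O4' O 5.7145 -2.7385 1.3189
B 1 DG C4' C 7.1212 -3.2027 1.2116
B 1 DG C2' C 6.3970 -2.2825 -0.8877
B 1 DG C3' C 7.4301 -3.2374 -0.3113
B 1 DG O3' O 7.2487 -4.5542 -0.8355
B 1 DG C5' C 8.0596 -2.2231 1.9188
B 1 DG C1' C 5.1991 -2.4987 -0.0000
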