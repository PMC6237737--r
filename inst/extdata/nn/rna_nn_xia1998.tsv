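# RNA Watson-Crick nearest-neighbor parameters.
# Source: Xia et al. (1998) Biochemistry 37:14719. 1 M NaCl reference.
# doublet = 5'XY3'/3'WZ5' with the bottom strand written aligned
# (3'->5'), so W pairs X and Z pairs Y. dH kcal/mol, dS cal/mol/K.
doublet	dH	dS
AA/UU	-6.82	-19.0
AU/UA	-9.38	-26.7
UA/AU	-7.69	-20.5
CU/GA	-10.48	-27.1
CA/GU	-10.44	-26.9
GU/CA	-11.40	-29.5
GA/CU	-12.44	-32.5
CG/GC	-10.64	-26.7
GG/CC	-13.39	-32.7
GC/CG	-14.88	-36.9
init	3.61	-1.5
term_AU	3.72	10.5
sym	0.0	-1.4
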