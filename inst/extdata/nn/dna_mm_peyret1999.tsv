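# DNA G.G and T.T single-internal-mismatch nearest-neighbor parameters.
# Source: Peyret, Seneviratne, Allawi & SantaLucia (1999) Biochemistry
# 38:3468 (like-with-like mismatches). 1 M NaCl reference state.
# doublet = 5'XY3'/3'WZ5'; the flipped orientation 5'ZW3'/3'YX5' is
# equivalent. dH kcal/mol, dS cal/mol/K.
doublet	dH	dS
AG/TG	-3.1	-9.5
CG/GG	-4.9	-15.3
GG/CG	-6.0	-15.8
TG/AG	1.6	3.6
AT/TT	-2.7	-10.8
CT/GT	-5.0	-15.8
GT/CT	-2.2	-8.4
TT/AT	0.2	-1.5
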