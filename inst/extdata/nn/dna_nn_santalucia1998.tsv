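# DNA Watson-Crick nearest-neighbor parameters, unified set.
# Source: SantaLucia (1998) PNAS 95:1460; Allawi & SantaLucia (1997)
# Biochemistry 36:10581. 1 M NaCl reference state.
# doublet = 5'XY3'/3'WZ5'. dH kcal/mol, dS cal/mol/K.
doublet	dH	dS
AA/TT	-7.9	-22.2
AT/TA	-7.2	-20.4
TA/AT	-7.2	-21.3
CA/GT	-8.5	-22.7
GT/CA	-8.4	-22.4
CT/GA	-7.8	-21.0
GA/CT	-8.2	-22.2
CG/GC	-10.6	-27.2
GC/CG	-9.8	-24.4
GG/CC	-8.0	-19.9
init_AT	2.3	4.1
init_GC	0.1	-2.8
sym	0.0	-1.4
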