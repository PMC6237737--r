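# Synthetic Hoogsteen pair template A(syn)-U, form A sugars.
# Constructed geometry (data-raw/make_templates.py); not experimental coordinates.
chain resno resname atom element x y z
A 1 A N9 N -2.4487 -5.9158 0.0000
A 1 A C8 C -1.0860 -5.8949 0.0000
A 1 A N7 N -0.6601 -4.6655 0.0000
A 1 A C5 C -1.7186 -3.8212 0.0000
A 1 A C6 C -1.8692 -2.4241 0.0000
A 1 A N1 N -3.0977 -1.9190 0.0000
A 1 A C2 C -4.1584 -2.7046 0.0000
A 1 A N3 N -4.0668 -4.0174 0.0000
A 1 A C4 C -2.8794 -4.6131 0.0000
A 1 A N6 N -0.7623 -1.5933 0.0000
A 1 A O4' O -4.1348 -7.1179 -1.1749
A 1 A C4' C -5.5474 -7.0974 -0.7392
A 1 A C2' C -4.2399 -7.0847 1.2168
A 1 A C3' C -5.5127 -6.5172 0.6550
A 1 A O3' O -6.6419 -6.9494 1.4156
A 1 A C5' C -6.3796 -6.2123 -1.6682
A 1 A O2' O -4.4546 -8.4031 1.7243
A 1 A C1' C -3.2967 -7.1094 0.0000
B 1 U N1 N 4.3497 -5.7080 -0.0000
B 1 U C2 C 3.0131 -5.8438 -0.0000
B 1 U N3 N 2.2082 -4.7640 -0.0000
B 1 U C4 C 2.7361 -3.5232 -0.0000
B 1 U C5 C 4.1421 -3.3673 -0.0000
B 1 U C6 C 4.9259 -4.4669 -0.0000
B 1 U O2 O 2.5233 -6.9557 -0.0000
B 1 U O4 O 2.0083 -2.5465 -0.0000
B 1 U O4' O 6.5108 -6.5715 0.5082
B 1 U C4' C 7.5041 -6.8473 -0.5514
B 1 U C2' C 5.3988 -7.4060 -1.4411
B 1 U C3' C 6.7164 -6.8035 -1.8395
B 1 U O3' O 7.3495 -7.5880 -2.8515
B 1 U C5' C 8.5948 -5.7751 -0.5526
B 1 U O2' O 5.4633 -8.8330 -1.4786
B 1 U C1' C 5.2008 -6.9011 -0.0000
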