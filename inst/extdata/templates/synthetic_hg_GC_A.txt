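# Synthetic Hoogsteen pair template G(syn)-C, form A sugars.
# Constructed geometry (data-raw/make_templates.py); not experimental coordinates.
chain resno resname atom element x y z
A 1 G N9 N -1.9367 -3.5468 0.0000
A 1 G C8 C -0.6105 -3.8681 0.0000
A 1 G N7 N 0.1067 -2.7822 0.0000
A 1 G C5 C -0.7142 -1.7032 0.0000
A 1 G C6 C -0.5023 -0.3048 0.0000
A 1 G N1 N -1.5815 0.5073 0.0000
A 1 G C2 C -2.8380 -0.0189 0.0000
A 1 G N3 N -3.0484 -1.3157 0.0000
A 1 G C4 C -2.0286 -2.1816 0.0000
A 1 G O6 O 0.6268 0.1555 0.0000
A 1 G N2 N -3.9158 0.8307 0.0000
A 1 G O4' O -3.8693 -4.2919 -1.1749
A 1 G C4' C -5.2324 -3.9206 -0.7392
A 1 G C2' C -3.9628 -4.2336 1.2168
A 1 G C3' C -5.0544 -3.3672 0.6550
A 1 G O3' O -6.2556 -3.5049 1.4156
A 1 G C5' C -5.8182 -2.8563 -1.6682
A 1 G O2' O -4.4988 -5.4571 1.7243
A 1 G C1' C -3.0554 -4.4922 0.0000
B 1 C N1 N 4.3497 -5.7080 -0.0000
B 1 C C2 C 3.0123 -5.8412 -0.0000
B 1 C N3 N 2.2143 -4.7742 -0.0000
B 1 C C4 C 2.7230 -3.5492 -0.0000
B 1 C C5 C 4.1222 -3.3758 -0.0000
B 1 C C6 C 4.9189 -4.4701 -0.0000
B 1 C O2 O 2.5198 -6.9574 -0.0000
B 1 C N4 N 1.8906 -2.4546 -0.0000
B 1 C O4' O 6.5104 -6.5710 0.5082
B 1 C C4' C 7.5038 -6.8469 -0.5514
B 1 C C2' C 5.3985 -7.4056 -1.4411
B 1 C C3' C 6.7161 -6.8030 -1.8395
B 1 C O3' O 7.3491 -7.5875 -2.8515
B 1 C C5' C 8.5944 -5.7747 -0.5526
B 1 C O2' O 5.4629 -8.8326 -1.4786
B 1 C C1' C 5.2004 -6.9006 -0.0000
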