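# Synthetic idealized fiber nucleotide templates, form A (ribo).
# Constructed geometry (data-raw/make_templates.py); not experimental coordinates.
# twist 32.7 rise 2.81
resname atom element x y z
A N9 N -4.5153 -3.8709 0.0000
A C8 C -4.9015 -2.5640 0.0000
A N7 N -3.8549 -1.7910 0.0000
A C5 C -2.7335 -2.5497 0.0000
A C6 C -1.3550 -2.2770 0.0000
A N1 N -0.5067 -3.2992 0.0000
A C2 C -0.9405 -4.5458 0.0000
A N3 N -2.2208 -4.8497 0.0000
A C4 C -3.1434 -3.8938 0.0000
A N6 N -0.8919 -0.9729 0.0000
A O4' O -6.7712 -4.6129 -0.1698
A C4' C -7.5399 -5.0351 1.0204
A C2' C -5.3258 -5.7551 1.3595
A C3' C -6.5054 -5.2025 2.1083
A O3' O -6.9550 -6.1250 3.1020
A C5' C -8.5568 -3.9603 1.4077
A O2' O -5.4470 -7.1697 1.1973
A O5' O -7.8699 -2.7946 1.8623
A P P -8.9408 -1.5926 1.8656
A OP1 O -10.0582 -1.9309 2.7735
A OP2 O -9.5068 -1.3752 0.3749
A C1' C -5.4019 -5.0361 0.0000
G N9 N -4.5153 -3.8709 0.0000
G C8 C -4.9040 -2.5629 0.0000
G N7 N -3.8563 -1.7911 0.0000
G C5 C -2.7367 -2.5556 0.0000
G C6 C -1.3509 -2.2724 0.0000
G N1 N -0.4847 -3.3087 0.0000
G C2 C -0.9459 -4.5905 0.0000
G N3 N -2.2302 -4.8670 0.0000
G C4 C -3.1471 -3.8928 0.0000
G O6 O -0.9490 -1.1213 0.0000
G N2 N -0.0422 -5.6234 0.0000
G O4' O -6.7715 -4.6133 -0.1698
G C4' C -7.5402 -5.0355 1.0204
G C2' C -5.3261 -5.7555 1.3595
G C3' C -6.5058 -5.2030 2.1083
G O3' O -6.9553 -6.1254 3.1020
G C5' C -8.5571 -3.9608 1.4077
G O2' O -5.4474 -7.1701 1.1973
G O5' O -7.8702 -2.7951 1.8623
G P P -8.9412 -1.5931 1.8656
G OP1 O -10.0585 -1.9313 2.7735
G OP2 O -9.5071 -1.3756 0.3749
G C1' C -5.4022 -5.0366 0.0000
C N1 N -4.5153 -3.8709 0.0000
C C2 C -3.1826 -4.0453 0.0000
C N3 N -2.3521 -3.0034 0.0000
C C4 C -2.8227 -1.7633 0.0000
C C5 C -4.2159 -1.5468 0.0000
C C6 C -5.0460 -2.6161 0.0000
C O2 O -2.7247 -5.1761 0.0000
C N4 N -1.9569 -0.6949 0.0000
C O4' O -6.7717 -4.6135 -0.1698
C C4' C -7.5403 -5.0357 1.0204
C C2' C -5.3262 -5.7557 1.3595
C C3' C -6.5059 -5.2031 2.1083
C O3' O -6.9554 -6.1256 3.1020
C C5' C -8.5573 -3.9610 1.4077
C O2' O -5.4475 -7.1703 1.1973
C O5' O -7.8703 -2.7953 1.8623
C P P -8.9413 -1.5933 1.8656
C OP1 O -10.0587 -1.9315 2.7735
C OP2 O -9.5073 -1.3758 0.3749
C C1' C -5.4023 -5.0367 0.0000
U N1 N -4.5153 -3.8709 0.0000
U C2 C -3.1835 -4.0478 0.0000
U N3 N -2.3456 -2.9934 0.0000
U C4 C -2.8350 -1.7369 0.0000
U C5 C -4.2355 -1.5378 0.0000
U C6 C -5.0528 -2.6127 0.0000
U O2 O -2.7281 -5.1743 0.0000
U O4 O -2.0775 -0.7831 0.0000
U O4' O -6.7720 -4.6140 -0.1698
U C4' C -7.5407 -5.0361 1.0204
U C2' C -5.3266 -5.7562 1.3595
U C3' C -6.5062 -5.2036 2.1083
U O3' O -6.9558 -6.1261 3.1020
U C5' C -8.5576 -3.9614 1.4077
U O2' O -5.4478 -7.1707 1.1973
U O5' O -7.8707 -2.7957 1.8623
U P P -8.9417 -1.5937 1.8656
U OP1 O -10.0590 -1.9319 2.7735
U OP2 O -9.5076 -1.3762 0.3749
U C1' C -5.4027 -5.0372 0.0000
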