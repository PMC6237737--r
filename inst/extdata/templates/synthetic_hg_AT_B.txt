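# Synthetic Hoogsteen pair template DA(syn)-DT, form B sugars.
# Constructed geometry (data-raw/make_templates.py); not experimental coordinates.
chain resno resname atom element x y z
A 1 DA N9 N -2.4320 -1.1937 0.0000
A 1 DA C8 C -1.0703 -1.2151 0.0000
A 1 DA N7 N -0.6067 0.0007 0.0000
A 1 DA C5 C -1.6392 0.8777 0.0000
A 1 DA C6 C -1.7469 2.2782 0.0000
A 1 DA N1 N -2.9604 2.8203 0.0000
A 1 DA C2 C -4.0442 2.0682 0.0000
A 1 DA N3 N -3.9927 0.7532 0.0000
A 1 DA C4 C -2.8233 0.1209 0.0000
A 1 DA N6 N -0.6155 3.0753 0.0000
A 1 DA O4' O -4.1535 -2.3481 -1.1677
A 1 DA C4' C -5.5126 -2.8170 -0.7951
A 1 DA C2' C -4.2471 -2.3086 1.1844
A 1 DA C3' C -5.4384 -3.1339 0.7248
A 1 DA O3' O -5.2020 -4.5263 0.9414
A 1 DA C5' C -6.5442 -1.7178 -1.0558
A 1 DA C1' C -3.3175 -2.3615 0.0000
B 1 DT N1 N 4.3490 -1.3069 -0.0000
B 1 DT C2 C 2.9415 -1.4117 -0.0000
B 1 DT N3 N 2.2568 -0.1921 -0.0000
B 1 DT C4 C 2.8144 1.0776 -0.0000
B 1 DT C5 C 4.3013 1.1070 -0.0000
B 1 DT C6 C 4.9599 -0.0594 -0.0000
B 1 DT O2 O 2.3335 -2.4837 -0.0000
B 1 DT O4 O 2.1512 2.1110 -0.0000
B 1 DT C7 C 4.9787 2.4397 -0.0000
B 1 DT O4' O 5.6971 -2.7142 1.3189
B 1 DT C4' C 7.1039 -3.1784 1.2116
B 1 DT C2' C 6.3796 -2.2582 -0.8877
B 1 DT C3' C 7.4128 -3.2131 -0.3113
B 1 DT O3' O 7.2313 -4.5299 -0.8355
B 1 DT C5' C 8.0422 -2.1988 1.9188
B 1 DT C1' C 5.1817 -2.4744 -0.0000
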