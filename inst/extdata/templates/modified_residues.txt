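# Modified-nucleotide whitelist: residue name -> canonical parent base.
# Editable; used by parent_base()/is_purine() for survey and stacking
# replacement of modified bases by their canonical parents.
resname parent
1MA A
MA6 A
6MA A
2MA A
1MG G
2MG G
M2G G
7MG G
OMG G
YG  G
I   G
DI  G
8OG G
BGM G
8BG G
BRG G
IGU G
OMC C
5MC C
5CM C
5BU U
BRU U
UMS U
OMU U
5MU U
PSU U
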