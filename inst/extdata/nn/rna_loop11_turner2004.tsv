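# RNA 1x1 internal loop (single internal mismatch) parameters for U.U
# and G.G mismatches closed by Watson-Crick pairs on both sides.
# Source: Turner-2004 rule set (Mathews et al. (2004) PNAS 101:7287 and
# the Turner lab compilation distributed with common secondary-structure
# packages). x5/y3 are the top-strand bases 5' and 3' of the mismatch;
# closing pairs are x5 with its complement and y3 with its complement.
# dG37 kcal/mol at 37 C, dH kcal/mol; dS = (dH - dG37)/310.15 * 1000.
mismatch	x5	y3	dG37	dH
UU	A	A	1.5	-3.9
UU	A	C	0.8	-12.3
UU	A	G	0.8	-8.9
UU	A	U	1.2	-7.3
UU	C	A	1.2	-5.5
UU	C	C	-0.1	-13.9
UU	C	G	0.4	-10.5
UU	C	U	0.8	-8.9
UU	G	A	1.2	-8.9
UU	G	C	-0.6	-17.3
UU	G	G	-0.1	-13.9
UU	G	U	0.8	-12.3
UU	U	A	1.7	-0.5
UU	U	C	1.2	-8.9
UU	U	G	1.2	-5.5
UU	U	U	1.5	-3.9
GG	A	A	-0.7	-8.3
GG	A	C	-1.4	-13.4
GG	A	G	-1.4	-13.4
GG	A	U	-0.7	-8.3
GG	C	A	-1.4	-13.4
GG	C	C	-2.2	-18.4
GG	C	G	-1.4	-18.4
GG	C	U	-1.4	-13.4
GG	G	A	-1.4	-13.4
GG	G	C	-2.3	-18.4
GG	G	G	-2.2	-18.4
GG	G	U	-1.4	-13.4
GG	U	A	-0.7	-8.3
GG	U	C	-1.4	-13.4
GG	U	G	-1.4	-13.4
GG	U	U	-0.7	-8.3
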