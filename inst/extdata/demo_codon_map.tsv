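codon	species	wobble_factor
GCU	Ala-AGC	1
GCC	Ala-AGC	0.64
GGU	Gly-ACC	1
GGC	Gly-ACC	0.64
AAA	Lys-UUU	1
AGA	Arg-UCU	1
GAU	Asp-AUC	1
GAA	Glu-UUC	1
UUA	Leu-UAA	1
UCU	Ser-AGA	1
ACU	Thr-AGU	1
GUU	Val-AAC	1
UUU	Phe-AAA	1
CCA	Pro-UGG	1
AAU	Asn-AUU	1
AUU	Ile-AAU	1
CAA	Gln-UUG	1
CAG	Gln-CUG	1
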