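amino_acid	E0	kcat	Km
Ala	100	0.150032328	100
Gly	100	0.166486188	100
Lys	100	0.111013465	100
Arg	100	0.0728571429	100
Asp	100	0.111013465	100
Glu	100	0.113974403	100
Leu	100	0.107957467	100
Ser	100	0.118464229	100
Thr	100	0.09898307	100
Val	100	0.106529183	100
Phe	100	0.124478134	100
Pro	100	0.0915606469	100
Asn	100	0.09898307	100
Ile	100	0.0900210084	100
Gln	100	0.00514285714	100
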