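species	anticodon	amino_acid	copies
Ala-AGC	AGC	Ala	928
Gly-ACC	ACC	Gly	1086
Lys-UUU	UUU	Lys	557
Arg-UCU	UCU	Arg	350
Asp-AUC	AUC	Asp	557
Glu-UUC	UUC	Glu	586
Leu-UAA	UAA	Leu	529
Ser-AGA	AGA	Ser	629
Thr-AGU	AGU	Thr	443
Val-AAC	AAC	Val	514
Phe-AAA	AAA	Phe	686
Pro-UGG	UGG	Pro	371
Asn-AUU	AUU	Asn	443
Ile-AAU	AAU	Ile	357
Gln-UUG	UUG	Gln	350
Gln-CUG	CUG	Gln	350
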