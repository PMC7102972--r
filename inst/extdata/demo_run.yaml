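tables:
  transcriptome: demo_transcriptome.tsv
  trna: demo_trna.tsv
  codon_map: demo_codon_map.tsv
  synthetases: demo_synthetases.tsv
params:
  W: 9
  beta: 10.0
  gamma: 0.0005
  R_total: 100
  R_star: 91.6
  lambda_scale: 0.0208564
  t_end: 60.0
  burn_in: 15.0
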