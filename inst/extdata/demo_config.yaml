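# Demo analysis: simulate a small dataset (with coverage tracks) and run
# every stage. Override `outdir` when launching programmatically.
seed: 42
dpsi: 0.1
p_max: 0.01
fdr_max: 0.05
alpha: 0.05
k: 6
floor_bp: 100
mirror_cos: -0.8
sim:
  n_genes: 150
  exons_per_gene: [5, 8]
  with_coverage: true
  intron_mean: 800
  as_intron_mean: 1500
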