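# Demonstration pipeline configuration: simulate a small cohort and run the
# full screen -> dereplication -> GNN -> classification workflow.
out_dir: demo_run
cutoff: 90
linkage: single
threshold: 1.0e-6
strict_threshold: 1.0e-75
max_mismatches: 2
min_len: 300
max_len: 3000
simulate:
  seed: 1
  n_strains: 14
  n_producer_clades: 3
  strains_per_clade: [4, 3, 2]
  within_clade_identity: 0.93
  between_clade_identity: [0.33, 0.69]
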