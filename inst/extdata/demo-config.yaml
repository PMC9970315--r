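# Demo run: three planted TGFB1 -> mediator -> miR-378a-3p -> CTGF paths
# hidden among 20 decoy genes, plus the qPCR and serum-cohort statistics.
seed: 7
out_dir: results/demo
mode: synthetic
min_tools: 3
max_depth: 4
network:
  planted_paths:
    - [TGFB1, SMAD3, miR-378a-3p, CTGF]
    - [TGFB1, HIF1A, miR-378a-3p, CTGF]
    - [TGFB1, TRIM25, miR-378a-3p, CTGF]
  mirnas: [miR-378a-3p]
  tfs: [SMAD3, HIF1A, TRIM25]
  n_decoy_genes: 20
  n_tfs: 3
  n_mirnas: 2
  ppi_edge_prob: 0.15
qpcr:
  genes: [TGFB1, miR-378a-3p, CTGF, GAPDH]
  reference_gene: GAPDH
  control_group: control
  n_replicates: 6
  ct_noise_sd: 0.25
  folds:
    OM:
      TGFB1: 0.42
      miR-378a-3p: 0.68
      CTGF: 0.58
cohort:
  default: true
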