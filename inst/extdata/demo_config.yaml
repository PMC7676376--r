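# demo pipeline configuration: a small simulated 16-study collection with
# three planted down-regulated genes, plus a synthetic literature export
seed: 20200728
sim:
  n_genes: 200
  n_planted: 3
  planted_lfc: -1.8
  tau2: 0.05
  sigma2: 0.25
  coverage_prob: 0.95
relations:
  n_universe: 5000
  n_disease_a: 120
  n_disease_b: 260
  n_overlap: 40
  min_refs: 3
selection:
  min_n: 10
mega:
  p_max: 1.0e-7
  lfc_min_abs: 1
  min_studies: 2
enrichment:
  n_sets: 40
  q_threshold: 0.005
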