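# Example pipeline configuration: a small synthetic screen run end to end.
# Usage: Rscript scripts/priorselect run-all --config example-config.yaml --out results/
seed: 1
synthetic:
  n_cell_lines: 120
  n_genes: 300
  n_drugs: 8
  n_pathways: 8
  n_signatures: 6
  signature_size_range: [5, 10]
  mechanism_mix:
    target_expression: 0.4
    target_mutation: 0.2
    polygenic: 0.1
    "null": 0.3
  effect_size: 0.3
  noise_sd: 0.05
strategies: [OT, PG, OT+S, PG+S, GW, GW_SEL_EN]
model_families: [en]
signature_threshold: 0.1
exclusion_epsilon: 0.01
protocol:
  test_fraction: 0.3
  cv_folds: 3
  n_repetitions: 5
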