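# Demo pipeline configuration: 300 simulated genes, five planted response
# clusters (including a transient up-then-down profile), 500 ensemble
# iterations. Mirrors the pipeline_config() schema.
seed: 42
outdir: samclust_demo
stages: [simulate, call_degs, cluster, enrich, summarize]
simulate:
  n_genes: 300
  frac_enriched: 0.2
  effect_size: 2
  n_replicates: 6
  dispersion: 0.1
  fc_noise_sd: 0.4
  genes_per_cluster: 60
  profiles:
    rev_up:        {REV_6h:  2.0, REV_16h:  2.0, KAN1_6h:  0.0, KAN1_16h:  0.0}
    rev_down:      {REV_6h: -2.0, REV_16h: -2.0, KAN1_6h:  0.0, KAN1_16h:  0.0}
    rev_transient: {REV_6h:  1.7, REV_16h: -1.4, KAN1_6h:  0.0, KAN1_16h:  0.0}
    kan1_up:       {REV_6h:  0.0, REV_16h:  0.0, KAN1_6h:  2.0, KAN1_16h:  2.0}
    kan1_down:     {REV_6h:  0.0, REV_16h:  0.0, KAN1_6h: -2.0, KAN1_16h: -2.0}
  n_terms: 20
ensemble:
  n_iterations: 500
  k_min: 3
  subsample_min_frac: 0.8
  kmeans_max_iter: 500
  kmeans_restarts: 20
cluster:
  retain_frac: 0.65
  n_trials: 100
  damping: 0.85
enrich:
  p_cutoff: 0.05
  min_overrep: 5
  min_annotated: 5
thresholds:
  lfc_min: 1
  padj_max: 0.05
  strict: true
  fold_cutoff: 1.5
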