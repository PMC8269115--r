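# Demo pipeline configuration: simulate a small cohort and run every stage.
# Usage: run_pipeline(system.file("extdata", "demo_config.yaml", package = "lipodriver"))
# (set out_dir to a writable location first, e.g. via pipeline_config())
seed: 1
out_dir: lipodriver_demo
simulate:
  n_genes: 600
  n_tfs: 30
cnv:
  n_perm: 500
screen:
  cor_threshold: 0.6
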