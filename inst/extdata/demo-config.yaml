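# Demonstration pipeline configuration (synthetic cohort).
# Run with: run_pipeline(system.file("extdata/demo-config.yaml",
#                                    package = "stopsignal"))
seed: 20260928
units: s
design:
  n_trials: 300
  n_blocks: 6
cohort:
  n_subjects: 8
  conditions: [rDLPFC, rIFG, sham]
sampler:
  chains: 2
  iter: 3000
  burn: 1500
io:
  out_dir: stopsignal-demo
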