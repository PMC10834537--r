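# Demonstration configuration: generates the shipped deterministic demo
# datasets and runs the full pipeline on them.
data:
  demo: true
alpha: 0.05
fdr_threshold: 0.05
min_count: 3
point_estimate_only: false
mc_draws: 10000
window_days: 365
run_metalab: true
seed: 20240201
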