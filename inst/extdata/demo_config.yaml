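# Demo run configuration for the packaged synthetic 60-animal cohort.
input: inst/extdata/synthetic_demo_cohort.tsv
out_dir: demo_results
traits: [growth_rate, leg_yield, vgr]
alpha: 0.05
include_p: 0.20
diplotype_min_freq: 0.05
simulate:
  seed: 60
  n_progeny: 60
  n_sires: 4
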