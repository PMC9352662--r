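# Study configuration for the synthetic-world analysis.
# Every script in analysis/ reads this file; override the seed or output
# directory on the command line, e.g.
#   Rscript analysis/01_simulate.R --seed 7 --outdir results/run_s7
seed: 1
world:
  n_species: 2000
  n_causal: 3
  n_noise: 20
  n_count: 2
  dd_fraction: 0.2
folds: 10
boruta_R: 50
boruta_alpha: 0.01
importance_reps: 50
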