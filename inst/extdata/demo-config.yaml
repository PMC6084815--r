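# bundled demo: full pipeline on a small simulated twin cohort (< 1 minute).
# per-site vectors recycle across sites, giving a mix of heritable/variable,
# weakly heritable, non-variable hypermethylated, and hypomethylated sites.
simulation:
  n_MZ: 100
  n_DZ: 80
  n_sites: 200
  A_true: [0.70, 0.25, 0.05, 0.45]
  C_true: [0.10, 0.15, 0.25, 0.05]
  E_true: [0.20, 0.60, 0.70, 0.50]
  mu_beta: [0.50, 0.30, 0.90, 0.15]
  total_sd: [0.08, 0.03, 0.01, 0.04]
  scale_mode: linear-clip
  mqtl_spec:
    fraction: 0.2
    maf: 0.25
    effect: 0.05
  exposure_spec:
    p_exposed: 0.3
    concordance: 0.7
    n_sites: 10
    effect: -0.1
thresholds:
  variable: 0.05
  intermediate: [0.20, 0.80]
  a_high: 0.8
  covariation: 0.5
  dmp: 1.0e-7
out_dir: twinmeth_demo_out
seed: 42
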