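# Example configuration for grmpart::run_pipeline().
# All thresholds shown are the package defaults.
simulate:
  n_individuals: 300
  n_variants: 1500
  n_chromosomes: 2
  chromosome_length_bp: 50000000
  founder_pool_size: 400
  switch_rate: 1.0e-8
  maf_spectrum:
    kind: uniform
    lo: 0.001
    hi: 0.5
  seed: 20
  pedigree:
    n_founders: 100
    n_generations: 2
    offspring_per_mating: 2
  architecture:
    n_causal: 800
    alpha: 0
    target_h2: 0.5
    reliability_lo: 0.8
    reliability_hi: 0.95
qc:
  min_individual_call_rate: 0.85
  min_locus_call_rate: 0.95
  hwe_p_min: 1.0e-5
  maf_min: 0.001
stratify:
  maf_boundaries: [0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5]
  n_ld_groups: 0
  ld_window_bp: 20000000
models:
  - greml-ms
  - reml-grm
  - reml-ped
  - reml-pedgrm
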