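# Example end-to-end workflow config for `run_pipeline()` /
# `cybospec.R run`. Uses the synthetic trajectory generator; replace the
# `trajectory` block with `path:` + `topology:` for real data, and add a
# `pmm: {qm_reference: qmref.dat}` block to compute perturbed band
# positions instead of supplying lambda_pmm below.
trajectory:
  synthetic_spec:
    regimes:
      - {hb_count: 2, r_mean: 1.8, r_sd: 0.1, theta_sd: 5, dwell: 0.45}
      - {hb_count: 1, r_mean: 1.8, r_sd: 0.1, theta_sd: 5, dwell: 0.35}
      - {hb_count: 0, r_mean: 1.8, r_sd: 0.1, theta_sd: 5, dwell: 0.20}
    n_frames: 80
    n_solvent: 5
    dt: 10
    seed: 17

clustering:
  stride_ps: 10        # ps between frames kept for clustering
  variance_target: 0.90
  k_min: 2
  k_max: 6
  seed: 7

grasp:
  budget: 9            # total representative frames across clusters
  alpha: 0.3
  n_restarts: 50

# externally computed per-cluster band positions (nm); weights are the
# cluster populations
shift_table:
  reference: DMF
  solvents:
    DMF:
      lambda_cf:      [475.0, 471.2, 486.7]
      lambda_c2qm:    [472.6, 449.8, 435.9]
      lambda_c0qm:    [462.0, 466.6, 440.0]
      lambda_pmm_vib: [474.5, 478.4, 453.3]
      lambda_pmm:     [465.5, 469.3, 445.1]
      weights:        [0.49, 0.36, 0.15]
    methanol:
      lambda_cf:      [462.5, 461.4]
      lambda_c2qm:    [448.3, 458.9]
      lambda_c0qm:    [455.3, 465.9]
      lambda_pmm_vib: [466.6, 471.7]
      lambda_pmm:     [458.1, 462.8]
      weights:        [0.56, 0.44]
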