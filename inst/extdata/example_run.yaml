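mode: synthetic
seed: 42
spacing_nm: [100, 100, 100]
analysis:
  smooth: true
  sigma_vox: [1.5, 1.5, 1.5]
  exclude_boundary: true
  exact_test_max_n: 12
  fdr_q: 0.05
  measure_diameter: true
groups:
  - region: DG
    age: young
    compartment: axon
    n_mito: 30
    mean_volume_um3: 0.12
    cv: 0.8
  - region: DG
    age: young
    compartment: dendrite
    n_mito: 30
    mean_volume_um3: 0.27
    cv: 0.8
  - region: DG
    age: young
    compartment: soma
    n_mito: 30
    mean_volume_um3: 0.19
    cv: 0.8
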