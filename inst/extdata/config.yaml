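species: synthetic sciurid
survey_dir: '.'
geometry: point
family: auto
n_bins: 10
covariates:
- name: shrub
  category: vegetation
- name: tpi
  category: topographic
- name: well
  category: anthropogenic
truncation:
  point: 0.1
  line: 0.05
thresholds:
  r: 0.7
  vif: 4.0
B: 30
R: 20
seed: 7
occasions:
- occ1
- occ2
out_dir: fixture_out

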