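# Example pipeline configuration: simulate the default paired-PET cohort
# and run the full analysis. Keys mirror run_config() / sim_config().
simulate:
  grid_dims: [20, 24, 20]
  n_subjects_per_group: [65, 75]
  n_components: 8
  coupled_pair: [1, 1]
  coupled_r: 0.6
  group_effect_components:
    m1: [2, 3]
    m2: [4, 5]
  group_effect_size: 0.8
  noise_sd: 0.1
  seed: 1
n_components: 8
alpha: 0.05
z_cutoff: 2.5
classify:
  k: 5
seed: 1
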