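template:
  name: toy_template
  length: 300
  primer_anchor: 280
  primer_len: 20
  obstacles:
  - stall_coord: 150
    p_stop: 0.5
    label: toy_stem
  sequence: AGCCCCGCGCAACACACCGACATTTTGTTCTATCTAAGACTACAATTCGCCCATTCAAGTCTTGTTCTCGGGCGTGCTCCACCGCGGGCACGCACTTTTCCTGGGTCGCCGTCTCGGCTTACCCCCCTGATCGAGACTCCTATACTGAGGTCCGCCAGAGTTCATAGAGTACTTGATGCGGTGACGCAGTCGTAATTTTTACGCTCGACGGTAACGGGGCATCCAGTATCAGAGTATTCTAATTTTATACTATGTGGTCTAAGATGGTTAAACCTAGGCTAGATTCTCATCCCCCGGGGT
profile:
  name: MRT
  step_rate: 25.0
  p_background_stop_per_nt: 0.0
  rebind_mode: processive_single_pass
  rebind_delay_rate: 1.0
  obstacle_overrides: ~
  obstacle_rescue: no
design:
  time_points: 10.0
  replicates: 1
  molecules_per_reaction: 20
  mode: multiple_cycle
  seed: 1
gel:
  migration_intercept: 100.0
  migration_slope: 30.0
  band_sigma: 0.6
  profile_bins: 1200
  intensity_per_molecule: 1.0
  min_length: 10
  max_length: 3500
  lane_jitter_sd: 0.2
error_model:
  substitution_rate: 0.05
  insertion_rate: 0.03
  deletion_rate: 0.05
  length_dropout_coef: 0.0003
seed: 42
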