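# Demo configuration for the end-to-end synthetic analysis.
seed: 7
cne_length: 32
n_species: 6
sub_rate: 0.02
n_compensatory_events: 2
retention_fraction: 0.4
read_depth: 10000
cage_spacing: 180
n_samples: 200
zero_fraction: 0.3
nc_fold: 3
noise_level: 0.05
couplings:
  HOXC11: 0.9
  HOXC12: 0.5
  HOXD10: -0.3
  HOXD11: -0.9
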