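# Default pavotrain run configuration. Any field may be omitted; defaults
# match default_run_config(). All lengths are abstract lattice units except
# the specimen lengths (cm).
seed: 1
lattice:
  alignment: zigzag        # zigzag | parallel
  row_sizes: alt_10_11     # alt_10_11 | const_10 | const_11
  first_row_size: 10
  n_rows: 18
  row_pitch: 1
  within_row_pitch: 1
expansion:
  fan_span: 180            # degrees
  base_radius: 5
  radial_pitch: 1
  midline_angle: 90
classify:
  n_fishtail_rows: 4
  n_minor_rows: 2
metrics:
  classes: eyespot
growth:
  rows_per_year: 1
  max_rows: 19
  n_fishtail_rows: 4
  n_minor_rows: 2
  length_asymptote: 150    # cm
  length_rate: 0.3         # per year
  first_row_size: 10
  ages: [0, 20]
specimens:
  species: cristatus       # cristatus | muticus
  n: 21
  damage_rate: 0.02
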