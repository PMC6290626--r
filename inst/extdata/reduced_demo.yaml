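# desk-scale demonstration configuration: short chain, monovalent salt,
# strong field; completes in seconds
Z: 1
E: 8.0
Nm: 16
n_salt: 8
box: [60, 16, 16]
coulomb_cutoff: 7.0
seed: 1

run:
  n_runs: 10
  seed0: 1
  equil_time: 25
  sample_dt: 0.5

analysis:
  gamma_window: [0.01, 0.1]
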