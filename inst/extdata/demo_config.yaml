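# Demo configuration: regenerates a small end-to-end run from one seed.
seed: 7
out_dir: results/demo
pulses:
  n_cells: 60
  hours: 14
  generator:
    pulse_rate: 1.0
    noise_cv: 0.04
bursts:
  n_cells: 25
  n_steps: 150
  w: auto
  n_boot: 16
  generator:
    k_on: 0.02
    k_off: 0.04
    r: 2
    w: 3
    dt: 90
    sigma_noise: 0.9
dose:
  generator:
    n_cells: 1500
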