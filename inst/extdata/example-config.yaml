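# Example run configuration: a small, moderately aligned network.
seed: 42
network:
  box_length: 6
  volume_fraction: 0.12
  diameter_mean: 0.5
  diameter_std: 0.05
  length_mean: 3
  length_std: 0.4
  tau_mean: 1.25
  tau_std: 0.1
  orientation:
    - axis: [0, 0, 1]
      k3d: 2
mechanics:
  fixed_end_steps: 2000
  max_steps: 15000
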