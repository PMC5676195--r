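# Version-pinned defaults for the simulated benchmark systems.
# The printed constraints these satisfy: stated resonance frequencies,
# unidirectional coupling chain, stability. Exact coupling values are a
# package choice (see the methods vignette).
three_node:
  fs: 120.0
  resonance_hz: [40.0, 10.0, 50.0]
  pole_radius: [0.9, 0.9, 0.9]
  order: 3
  couplings:
    - {from: 1, to: 2, lag: 2, value: 0.35}
    - {from: 2, to: 3, lag: 3, value: 0.35}
  innovation_var: [1.0, 1.0, 1.0]
  n_samples: 500
  n_realizations: 100
two_node:
  fs: 120.0
  transmitter_hz: 50.0
  receiver_hz: [10.0, 30.0, 50.0]
  pole_radius: [0.9, 0.9]
  order: 2
  couplings:
    - {from: 1, to: 2, lag: 1, value: 0.35}
  innovation_var: [1.0, 1.0]
  n_samples: 500
  n_realizations: 100
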