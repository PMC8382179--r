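# Example run configuration: every value shown equals the package default,
# so deleting any line leaves behaviour unchanged.
wing:
  stiffness_factor: 1.0
  damping_ratio: 0.02
kinematics:
  primary_freq: 25.0
  secondary_freq: 50.0
  secondary_rel_amplitude: 0.76
  flapping_noise_frac: 0.02
rotation:
  axis: yaw
  rate: 10.0
  rotation_noise_frac: 0.01
encoder:
  beta: 0.2
  alpha: 50.0
  refractory: 15.0
sspoc:
  m: 3
  lam: 0.9
  k: 10
run:
  duration: 3.0
  n_repeats: 10
  train_frac: 0.9
  direction: spanwise
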