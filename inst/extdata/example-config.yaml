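# Example end-to-end pipeline configuration for the tomoshot CLI:
#   tomoshot train --config example-config.yaml --out out/ --seed 7
# Sections mirror the constructor arguments of sim_config(),
# optics_params(), model_config(), train_config() and crf_params().
seed: 7
n_train_classes: 4
eval_n_way: [2]
eval_episodes: 200
sim:
  tomogram_shape: [170, 170, 110]
  n_particles: 150
  tilt_min: -60
  tilt_max: 60
  tilt_step: 2
  snr: .inf
  subtomo_size: 32
  voxel_size: 10
optics:
  enabled: false
  voltage: 300
  defocus: -5
  spherical_aberration: 2
  amplitude_contrast: 0.07
  mtf_cutoff: 0.4
  pixel_size: 10
model:
  channels: [2, 4, 8]
  fe_adapter: flatten
  head_monotone: true
train:
  n_way: 2
  epochs: 30
  episodes_per_epoch: 20
  lr: 0.001
  augment_poses: inplane
crf:
  w1: 1
  w2: 1
  sigma_alpha: 2
  sigma_beta: 0.5
  sigma_gamma: 1
  n_iterations: 5
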