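# Desk-scale plan consumed by every `adaunet` CLI subcommand.
seed: 1
variants: [unet, au_net, dau_net]
phantom:
  image_size: 64
  n_cases: 8
  slices_per_case: 4
  contrast: 0.3
  noise_sd: 0.05
  n_distractors: 3
  shape_irregularity: 0.3
  seed: 1
segmentor:
  depth: 4
  base_channels: 16
discriminator:
  channels: [64, 128, 256, 512, 1]
train:
  learning_rate: 0.0001
  adam_beta1: 0.9
  adam_beta2: 0.99
  batch_size: 1
  iterations: 300
  seed: 2
loss_weights:
  beta: 1
  gamma: 0.004
  epsilon: 0.1
  mu: 0.0004
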