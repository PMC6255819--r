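# Reference VGG-19-style architecture: 19 weight-bearing layers
# (16 conv + 3 dense) in five conv blocks separated by max pools.
# Shipped for layer-count parity with the full-scale network; the desk-scale
# default (desk_net_config()) is what the package actually synthesizes with.
input_channels: 1
weight_seed: 1
padding: zero
gram_layers: [1, 4, 7, 12, 17]
layers:
  - {kind: conv, out_channels: 64, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 64, kernel: 3, activation: relu}
  - {kind: pool, mode: max, size: 2}
  - {kind: conv, out_channels: 128, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 128, kernel: 3, activation: relu}
  - {kind: pool, mode: max, size: 2}
  - {kind: conv, out_channels: 256, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 256, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 256, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 256, kernel: 3, activation: relu}
  - {kind: pool, mode: max, size: 2}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: pool, mode: max, size: 2}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: conv, out_channels: 512, kernel: 3, activation: relu}
  - {kind: pool, mode: max, size: 2}
  - {kind: dense, out_channels: 4096, activation: relu}
  - {kind: dense, out_channels: 4096, activation: relu}
  - {kind: dense, out_channels: 1000, activation: none}
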