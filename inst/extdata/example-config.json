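{
  "generator": {
    "n_molecules": 40,
    "heavy_range": [3, 8],
    "seed": 7,
    "n_snapshots": 10,
    "conformations": true
  },
  "model": {
    "n_layers": 2,
    "hidden_dim": 24,
    "embedding_dim": 24,
    "pooling_hidden": 24,
    "pooling_dim": 16,
    "readout_hidden": 24,
    "seed": 1
  },
  "fit": {
    "epochs": 60,
    "lr": 0.002,
    "patience": 30,
    "n_boot": 200,
    "loss_weights": {"energy": 1, "charge": 0, "type": 0}
  }
}
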