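{
  "demo": {
    "seed": 1
  },
  "null": {
    "seed": 1,
    "effect_size": 1,
    "n_planted_pairs": 0
  },
  "strong-signal": {
    "seed": 1,
    "n_stations": 4,
    "samples_per_station": 10,
    "effect_size": 8,
    "n_effect_features": 30
  }
}
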