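{
  "prior": {
    "mean": 0,
    "precision": [
      [0.25]
    ],
    "labels": "theta"
  },
  "posterior": {
    "mean": 1,
    "precision": [
      [4]
    ],
    "labels": "theta"
  },
  "free_energy": 0,
  "meta": []
}
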