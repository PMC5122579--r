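{
  "variant": "depression_facilitation",
  "mode": "correlated",
  "samples": 50000,
  "seed": 1,
  "grid": []
}
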