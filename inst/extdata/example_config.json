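{
  "scenario": "donnan_novol",
  "overrides": {
    "settings": { "t_end": "20 min", "st": "1 ms" }
  },
  "out_dir": "results",
  "formats": ["csv", "json"]
}
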