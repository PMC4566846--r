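{
  "out_dir": "magicpop_demo",
  "seed": 1,
  "n_markers": 500,
  "n_lines": 60,
  "error_rate": 0.01,
  "missing_rate": 0.15,
  "stages": ["simulate", "reconstruct"]
}
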