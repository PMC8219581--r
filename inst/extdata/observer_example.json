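{
  "threshold": 0.015,
  "slope": 150,
  "guess_rate": 0.5,
  "lapse_rate": 0.02,
  "form": "logistic"
}
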