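# 80 Hz sub-Poissonian gamma carrier gated to the downward half of each
# cycle of a quasi-periodic 7 Hz theta train
process:
  kind: modulated
  shape: 31.62
  rate: 80
  modulator:
    shape: 31.62
    rate: 7
  modulator_period_s: 0.1429
  keep: [0.0, 0.5]
duration_s: 120
seed: 1
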