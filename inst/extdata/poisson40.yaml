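# 40 Hz Poisson event train (gamma renewal, a = 1)
process:
  kind: gamma
  shape: 1
  rate: 40
duration_s: 120
seed: 1
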