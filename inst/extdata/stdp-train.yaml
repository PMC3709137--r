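# STDP training on the randomized ten-ratio pulse sequence
pipeline: stdp-train
seed: 1
params:
  epochs: 300
  trials_per_ratio: 6
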