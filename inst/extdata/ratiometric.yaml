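# Ratiometric decoding of synthetic SAWR chemosensor transients
pipeline: ratiometric
seed: 1
params:
  pool: 8
  compression: 10
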