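# Regime comparison: FPA (all-to-all symmetric LN inhibition) vs LCA (sparse)
pipeline: regimes
seed: 1
params:
  amp: [1, 2]
  window: 50
  settle: 200
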