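# Minimal run configuration: unset keys take the reference-table defaults.
# Units: uM, nm, s.
simulation:
  ip3: 0.07
  duration: 700.0
  seed: 42
  mode: reduced
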