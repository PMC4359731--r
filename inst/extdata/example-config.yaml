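# Example lampswim configuration: a 4 s^-1, 2% activation experiment on
# the default calibrated body. Omitted keys take package defaults.
activation:
  frequency: 4.0
  strength: 2.0
solver:
  duration: 8.0
  samples_per_cycle: 200
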