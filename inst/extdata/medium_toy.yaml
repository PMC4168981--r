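# Toy-model growth medium: glucose + oxygen uptake, forced CO2 and biomass
# secretion (mmol/gDW/h). Uptakes are magnitudes applied as negative lower
# bounds on the exchange reactions.
uptakes:
  EX_glc: 10
  EX_o2: 25
forced:
  EX_co2: 0.1
  EX_bm: 0.01
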