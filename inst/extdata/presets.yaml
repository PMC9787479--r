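# Experiment presets: seed file + rule files + defaults for the four modeled
# networks. Iron-containing variants add the ionic seeds and the iron rule
# library on top of the iron-free configuration.
formose:
  seeds: seeds/formose.smi
  rules: [rules/formose.yaml]
  iron_rules: [rules/iron_redox.yaml]
  generations: 5
  mass_cap: 200
pyruvic:
  seeds: seeds/pyruvate.smi
  rules: [rules/pyruvate.yaml]
  iron_rules: [rules/iron_redox.yaml]
  generations: 5
  mass_cap: 200
glucose_degradation:
  seeds: seeds/glucose.smi
  rules: [rules/glucose.yaml]
  iron_rules: [rules/iron_redox.yaml]
  generations: 4
  mass_cap: 200
maillard:
  seeds: seeds/maillard.smi
  rules: [rules/maillard.yaml]
  iron_rules: [rules/iron_redox.yaml]
  generations: 3
  mass_cap: 200
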