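# Iron-induced mechanisms (a-g): two-electron organic redox steps coupled to
# Fe2+/Fe3+ interconversion, plus an iron-mediated sugar beta-elimination.
# Protons balance the electron transfers; literature-vetting ranges are kept
# as provenance metadata (anoxic water, moderate temperature and pH).
rules:

- name: "Fe+2 to Fe+3, A Keto Reduction of a Carboxylic Acid"
  iron_dependent: true
  provenance: {temperature_c: [25, 120], ph: [2, 12]}
  reactants:
  - atoms:
    - {id: c1, elem: C}
    - {id: o1, elem: O}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    - {id: o3, elem: O, minH: 1}
    bonds:
    - [c1, o1, 2]
    - [c1, c2, 1]
    - [c2, o2, 2]
    - [c2, o3, 1]
  coagents:
    consumed: {"[Fe+2]": 2, "[H+]": 2}
    produced: {"[Fe+3]": 2}
  transform:
    bonds:
    - [c1, o1, 1]
    hydrogens:
    - [c1, 1]
    - [o1, 1]

- name: "Fe+2 to Fe+3, Conversion of A Hydroxy Group of an aldehyde to A Keto group, Inverse"
  iron_dependent: true
  inverse_of: "Fe+3 to Fe+2, Conversion of A Hydroxy Group of an aldehyde to A Keto group"
  provenance: {temperature_c: [25, 120], ph: [2, 12]}
  reactants:
  - atoms:
    - {id: c1, elem: C, minH: 1}
    - {id: o1, elem: O}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    bonds:
    - [c1, o1, 2]
    - [c1, c2, 1]
    - [c2, o2, 2]
  coagents:
    consumed: {"[Fe+2]": 2, "[H+]": 2}
    produced: {"[Fe+3]": 2}
  transform:
    bonds:
    - [c2, o2, 1]
    hydrogens:
    - [c2, 1]
    - [o2, 1]

- name: "Fe+2 to Fe+3, Conversion of A Keto Group of an Acid to A Hydro group"
  iron_dependent: true
  provenance: {temperature_c: [25, 120], ph: [2, 12]}
  reactants:
  - atoms:
    - {id: c1, elem: C}
    - {id: o1, elem: O}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    - {id: o3, elem: O, minH: 1}
    bonds:
    - [c1, o1, 2]
    - [c1, c2, 1]
    - [c2, o2, 2]
    - [c2, o3, 1]
  coagents:
    consumed: {"[Fe+2]": 4, "[H+]": 4}
    produced: {"[Fe+3]": 4}
  transform:
    bonds:
    - [c1, o1, 0]
    hydrogens:
    - [c1, 2]
    - [o1, 2]

- name: "Fe+3 to Fe+2, Aldehyde to acid"
  iron_dependent: true
  provenance: {temperature_c: [25, 120], ph: [2, 12]}
  reactants:
  - atoms:
    - {id: c1, elem: C, minH: 1}
    - {id: o1, elem: O}
    bonds:
    - [c1, o1, 2]
  - exact: "O"
    ids: [ow]
  coagents:
    consumed: {"[Fe+3]": 2}
    produced: {"[Fe+2]": 2, "[H+]": 2}
  transform:
    bonds:
    - [c1, ow, 1]
    hydrogens:
    - [c1, -1]
    - [ow, -1]

- name: "Fe+3 to Fe+2, Conversion of A Hydro Group of an Acid to A Keto group"
  iron_dependent: true
  inverse_of: "Fe+2 to Fe+3, Conversion of A Keto Group of an Acid to A Hydro group"
  provenance: {temperature_c: [25, 120], ph: [2, 12]}
  reactants:
  - atoms:
    - {id: c1, elem: C, minH: 2}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    - {id: o3, elem: O, minH: 1}
    bonds:
    - [c1, c2, 1]
    - [c2, o2, 2]
    - [c2, o3, 1]
  - exact: "O"
    ids: [ow]
  coagents:
    consumed: {"[Fe+3]": 4}
    produced: {"[Fe+2]": 4, "[H+]": 4}
  transform:
    bonds:
    - [c1, ow, 2]
    hydrogens:
    - [c1, -2]
    - [ow, -2]

- name: "Fe+3 to Fe+2, Conversion of A Hydroxy Group of an aldehyde to A Keto group"
  iron_dependent: true
  provenance: {temperature_c: [25, 120], ph: [2, 12]}
  reactants:
  - atoms:
    - {id: c1, elem: C, minH: 1}
    - {id: o1, elem: O, minH: 1}
    - {id: c2, elem: C, minH: 1}
    - {id: o2, elem: O}
    bonds:
    - [c1, o1, 1]
    - [c1, c2, 1]
    - [c2, o2, 2]
  coagents:
    consumed: {"[Fe+3]": 2}
    produced: {"[Fe+2]": 2, "[H+]": 2}
  transform:
    bonds:
    - [c1, o1, 2]
    hydrogens:
    - [c1, -1]
    - [o1, -1]

- name: "Fe+3, B elimination from a sugar & Conversion to Acid"
  iron_dependent: true
  provenance: {temperature_c: [25, 120], ph: [2, 12]}
  reactants:
  - atoms:
    - {id: cb, elem: C}
    - {id: ob, elem: O, minH: 1}
    - {id: ca, elem: C, minH: 1}
    - {id: c1, elem: C, minH: 1}
    - {id: o1, elem: O}
    bonds:
    - [cb, ob, 1]
    - [cb, ca, 1]
    - [ca, c1, 1]
    - [c1, o1, 2]
  - exact: "O"
    ids: [ow]
  coagents:
    consumed: {"[Fe+3]": 2}
    produced: {"[Fe+2]": 2, "[H+]": 2}
  transform:
    bonds:
    - [cb, ob, 0]
    - [ca, cb, 2]
    - [c1, ow, 1]
    hydrogens:
    - [ob, 1]
    - [ca, -1]
    - [c1, -1]
    - [ow, -1]
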