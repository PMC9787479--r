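# Nitrogen chemistry for the glucose-glycine Maillard network: Strecker
# degradation of an alpha-amino acid by a 1,2-dicarbonyl (four substituent
# variants) and amide formation/hydrolysis. This is an explicit
# reconstruction: only the mechanisms named in the published frequency tables
# are encoded; the source's full Maillard list is not printed there.
rules:

- name: "Strecker Degradation Dicarbonyl, C, H, C, H"
  iron_dependent: false
  reactants:
  - atoms:
    - {id: n1, elem: "N", minH: 2}
    - {id: c1, elem: C, minH: 1}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    - {id: o3, elem: O, minH: 1}
    bonds:
    - [n1, c1, 1]
    - [c1, c2, 1]
    - [c2, o2, 2]
    - [c2, o3, 1]
  - atoms:
    - {id: c4, elem: C}
    - {id: o4, elem: O}
    - {id: c5, elem: C}
    - {id: o5, elem: O}
    - {id: c6, elem: C}
    - {id: c7, elem: C}
    bonds:
    - [c4, o4, 2]
    - [c4, c5, 1]
    - [c5, o5, 2]
    - [c4, c6, 1]
    - [c5, c7, 1]
  transform:
    bonds:
    - [c1, c2, 0]
    - [c2, o3, 2]
    - [n1, c1, 0]
    - [n1, c4, 1]
    - [c4, o4, 0]
    - [c1, o4, 2]
    hydrogens:
    - [o3, -1]
    - [c4, 1]

- name: "Strecker Degradation Dicarbonyl, C, H, H, C"
  iron_dependent: false
  reactants:
  - atoms:
    - {id: n1, elem: "N", minH: 2}
    - {id: c1, elem: C, minH: 1}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    - {id: o3, elem: O, minH: 1}
    bonds:
    - [n1, c1, 1]
    - [c1, c2, 1]
    - [c2, o2, 2]
    - [c2, o3, 1]
  - atoms:
    - {id: c4, elem: C}
    - {id: o4, elem: O}
    - {id: c5, elem: C, minH: 1}
    - {id: o5, elem: O}
    - {id: c6, elem: C}
    bonds:
    - [c4, o4, 2]
    - [c4, c5, 1]
    - [c5, o5, 2]
    - [c4, c6, 1]
  transform:
    bonds:
    - [c1, c2, 0]
    - [c2, o3, 2]
    - [n1, c1, 0]
    - [n1, c4, 1]
    - [c4, o4, 0]
    - [c1, o4, 2]
    hydrogens:
    - [o3, -1]
    - [c4, 1]

- name: "Strecker Degradation Dicarbonyl, H, H, C, H"
  iron_dependent: false
  reactants:
  - atoms:
    - {id: n1, elem: "N", minH: 2}
    - {id: c1, elem: C, minH: 1}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    - {id: o3, elem: O, minH: 1}
    bonds:
    - [n1, c1, 1]
    - [c1, c2, 1]
    - [c2, o2, 2]
    - [c2, o3, 1]
  - atoms:
    - {id: c4, elem: C, minH: 1}
    - {id: o4, elem: O}
    - {id: c5, elem: C}
    - {id: o5, elem: O}
    - {id: c7, elem: C}
    bonds:
    - [c4, o4, 2]
    - [c4, c5, 1]
    - [c5, o5, 2]
    - [c5, c7, 1]
  transform:
    bonds:
    - [c1, c2, 0]
    - [c2, o3, 2]
    - [n1, c1, 0]
    - [n1, c4, 1]
    - [c4, o4, 0]
    - [c1, o4, 2]
    hydrogens:
    - [o3, -1]
    - [c4, 1]

- name: "Strecker Degradation Dicarbonyl, H, H, H, C"
  iron_dependent: false
  reactants:
  - atoms:
    - {id: n1, elem: "N", minH: 2}
    - {id: c1, elem: C, minH: 1}
    - {id: c2, elem: C}
    - {id: o2, elem: O}
    - {id: o3, elem: O, minH: 1}
    bonds:
    - [n1, c1, 1]
    - [c1, c2, 1]
    - [c2, o2, 2]
    - [c2, o3, 1]
  - atoms:
    - {id: c4, elem: C, minH: 1}
    - {id: o4, elem: O}
    - {id: c5, elem: C, minH: 1}
    - {id: o5, elem: O}
    bonds:
    - [c4, o4, 2]
    - [c4, c5, 1]
    - [c5, o5, 2]
  transform:
    bonds:
    - [c1, c2, 0]
    - [c2, o3, 2]
    - [n1, c1, 0]
    - [n1, c4, 1]
    - [c4, o4, 0]
    - [c1, o4, 2]
    hydrogens:
    - [o3, -1]
    - [c4, 1]

- name: "Amide Formation Hydrolysis, C"
  iron_dependent: false
  combine_slack: 18
  reactants:
  - atoms:
    - {id: c1, elem: C}
    - {id: o1, elem: O}
    - {id: o2, elem: O, minH: 1}
    bonds:
    - [c1, o1, 2]
    - [c1, o2, 1]
  - atoms:
    - {id: n1, elem: "N", minH: 1}
    - {id: c3, elem: C}
    bonds:
    - [n1, c3, 1]
  transform:
    bonds:
    - [c1, o2, 0]
    - [c1, n1, 1]
    hydrogens:
    - [o2, 1]
    - [n1, -1]

- name: "Amide Formation Hydrolysis, C, Inverse"
  iron_dependent: false
  inverse_of: "Amide Formation Hydrolysis, C"
  reactants:
  - atoms:
    - {id: c1, elem: C}
    - {id: o1, elem: O}
    - {id: n1, elem: "N"}
    - {id: c3, elem: C}
    bonds:
    - [c1, o1, 2]
    - [c1, n1, 1]
    - [n1, c3, 1]
  - exact: "O"
    ids: [ow]
  transform:
    bonds:
    - [c1, n1, 0]
    - [c1, ow, 1]
    hydrogens:
    - [n1, 1]
    - [ow, -1]
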