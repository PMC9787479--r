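# Formose network rule set: the 31 shared C/H/O mechanisms plus the formose
# C-C coupling (umpolung addition of an aldehyde C-H across a carbonyl),
# which bootstraps glycolaldehyde from two formaldehyde molecules
# (32 iron-free rules).
include: [cho_core.yaml]
rules:
- name: "Formose C-C Coupling"
  iron_dependent: false
  combine_slack: 0
  reactants:
  - atoms:
    - {id: c1, elem: C, minH: 1}
    - {id: o1, elem: O}
    bonds:
    - [c1, o1, 2]
  - atoms:
    - {id: c3, elem: C}
    - {id: o3, elem: O}
    bonds:
    - [c3, o3, 2]
  transform:
    bonds:
    - [c1, c3, 1]
    - [c3, o3, 1]
    hydrogens:
    - [c1, -1]
    - [o3, 1]
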