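# Glucose-glycine Maillard network rule set: the C/H/O core plus the
# nitrogen chemistry reconstruction.
include: [cho_core.yaml, maillard_n.yaml]
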