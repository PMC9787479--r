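# ionic additions for iron-containing runs
[Fe+2]
[Fe+3]
[H+]
[OH-]
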