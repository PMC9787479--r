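network,iterations,iron_free,iron_containing
formose,5,23459,32523
pyruvic,5,9081,23232
glucose_degradation,4,7891,9438
maillard,3,2923,3417
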