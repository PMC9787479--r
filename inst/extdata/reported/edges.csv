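network,iterations,iron_free,iron_containing
formose,5,54525,81049
pyruvic,5,17446,45367
glucose_degradation,4,19271,23661
maillard,3,8856,10460
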