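network,generations,catalyzed,printed_percent
formose,5,1634,7
pyruvic,5,765,8.4
glucose_degradation,4,231,3
maillard,3,33,1.1
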