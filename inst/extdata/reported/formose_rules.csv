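rule,iron_free,iron_containing,printed_percent_change
B-G Unsaturated Acid Decarboxylation,12,54,350
A-B Unsaturated Acid Decarboxylation,5,17,240
A-Keto Acid Decarboxylation,78,187,140
"Ring Closure 5 membered O, O",398,946,138
"Michael Addition 0.2, Inverse",221,520,135
"Ring Closure 6 membered O, O",227,527,132
"Ring Closure 7 membered O, O",82,190,132
B Decarboxylation,106,222,109
"Benzilic Acid Rearrangement, Inverse",365,670,84
Benzilic Acid Rearrangement,326,592,82
"Knoevenagel H, Inverse",1830,3189,74
Canizzaro,242,417,72
"Hemiacetal Formation for 5 membered rings, Inverse",348,586,68
Hemiacetal Formation for 5 membered rings,2482,4082,64
"Canizzaro 2, HCHO (oxidation)",2731,4326,58
"Hemiacetal Formation for 6 membered rings, Inverse",135,211,56
Keto-enol migration twice,1884,2936,56
Retro Aldol,3756,5849,56
Elimination + enol to keto,3825,5926,55
Hemiacetal Formation for 6 membered rings,1500,2320,55
"Canizzaro 2, HCHO (reduction)",1691,2545,51
Hemiacetal Formation for 7 membered rings,599,896,50
"Knoevenagel C, Inverse",1623,2384,47
Elimination2,3966,5758,45
Hydration of C=C(O),522,753,44
"Hemiacetal Formation for 7 membered rings, Inverse",52,75,44
Knoevenagel H,5494,7576,38
Hydration of C(=O)C,1731,2359,36
Michael Addition 0.2,4327,5508,27
Knoevenagel C,5228,6484,24
Aldol Condensation,8739,10579,21
"Fe+2 to Fe+3, A Keto Reduction of a Carboxylic Acid",0,187,NA
"Fe+2 to Fe+3, Conversion of A Hydroxy Group of an aldehyde to A Keto group, Inverse",0,636,NA
"Fe+2 to Fe+3, Conversion of A Keto Group of an Acid to A Hydro group",0,183,NA
"Fe+3 to Fe+2, Aldehyde to acid",0,412,NA
"Fe+3 to Fe+2, Conversion of A Hydro Group of an Acid to A Keto group",0,251,NA
"Fe+3 to Fe+2, Conversion of A Hydroxy Group of an aldehyde to A Keto group",0,566,NA
"Fe+3, B elimination from a sugar & Conversion to Acid",0,130,NA
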