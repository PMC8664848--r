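name,unit,lower,upper,hard_lower,hard_upper
pH,-,6,9,0,14
Alkalinity,mg-eq/L,0.5,6.5,,
Hardness,mg-eq/L,,7,,
Mineralization,mg-eq/L,,1000,,
Ca,mg/L,,,,
Mg,mg/L,,50,,
Na,mg/L,,200,,
K,mg/L,,,,
NH4,mg/L,,2,,
HCO3,mg/L,,,,
Cl,mg/L,,350,,
NO3,mg/L,,45,,
NO2,mg/L,,3,,
PO4,mg/L,,3.5,,
SO4,mg/L,,500,,
Cr,mg/L,,0.05,,
Cu,mg/L,,1,,
Fe,mg/L,,0.3,,
Mn,mg/L,,0.1,,
Ni,mg/L,,0.1,,
Zn,mg/L,,5,,
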