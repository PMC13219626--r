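2
sensor@analyte contact dimer
C        0.000000       0.000000       0.000000
N        0.000000       0.000000       2.800000
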