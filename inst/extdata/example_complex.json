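{"label":"synthetic-complex","orbitals":{"energies_ev":[-8.8,-7.8,-6.8,-5.8,-4.8,-3.62,-2.62,-1.62,-0.62,0.38],"occupations":[2,2,2,2,2,0,0,0,0,0]},"energies":{"total":-17011.15,"units":"kcal/mol"},"geometry":{"elements":["C","N"],"coords":[[0,0,0],[0,0,2.8]],"charge":0,"label":"sensor@analyte contact dimer"},"excitations":[{"ev":1.61,"nm":770.088155279503,"f":0.2}]}
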