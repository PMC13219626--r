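{"label":"synthetic-sensor","orbitals":{"energies_ev":[-9.25,-8.25,-7.25,-6.25,-5.25,-3.58,-2.58,-1.58,-0.58,0.42],"occupations":[2,2,2,2,2,0,0,0,0,0]},"energies":{"total":-12000,"units":"kcal/mol"},"geometry":{"elements":"C","coords":[[0,0,0]],"charge":0,"label":"sensor site"},"excitations":[{"ev":2.37,"nm":523.140054852321,"f":0.2}]}
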