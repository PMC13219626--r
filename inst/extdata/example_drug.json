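{"label":"synthetic-drug","orbitals":{"energies_ev":[-9,-1],"occupations":[2,0]},"energies":{"total":-5000,"units":"kcal/mol"}}
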