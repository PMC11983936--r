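name: dimer 4a by double Friedlander condensation
reactants:
  - name: 2-aminobenzophenone
    formula: C13H11NO
    equivalents: 2
  - name: 4,4'-bicyclohexanedione
    formula: C12H18O2
    equivalents: 1
product:
  name: 4a
  formula: C38H32N2
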