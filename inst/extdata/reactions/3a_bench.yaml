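# Bench-scale monomer condensation with the masses actually charged.
name: monomer 3a, conventional bench scale
reactants:
  - name: 2-aminobenzophenone
    formula: C13H11NO
    equivalents: 1
    mass_g: 0.5
  - name: 4,4'-bicyclohexanedione
    formula: C12H18O2
    equivalents: 1
    mass_g: 0.49
auxiliaries:
  - name: hydrochloric acid
    role: catalyst
    mass_g: 0.06
product:
  name: 3a
  formula: C25H25NO
  mass_g: 0.48
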