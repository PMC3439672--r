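name: minimal_binding
readout_moiety: A
species:
- name: A
  role: monomer
  moieties:
    A: 1
- name: B
  role: monomer
  moieties:
    B: 1
- name: C
  role: complex
  moieties:
    A: 1
    B: 1
reactions:
- label: R1
  reactants:
    A: 1
    B: 1
  products:
    C: 1
initial_concentrations:
  A: 1.0
  B: 1.0
  C: 0.0
rates:
  R1:
    kf: 1.0
    kr: 1.0
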