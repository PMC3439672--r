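name: broken
readout_moiety: A
species:
- name: A
  role: monomer
  moieties:
    A: 1
reactions:
- label: R1
  reactants:
    A: 1
  products:
    Z: 1
initial_concentrations:
  A: 1.0
rates:
  R1:
    kf: 1.0
    kr: 0.0
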