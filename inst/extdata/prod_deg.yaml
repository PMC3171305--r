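name: prod_deg
species:
- {name: S1, initial: 1}
- {name: S2, initial: 40}
reactions:
- {reactants: {S1: 1}, products: {S1: 1, S2: 1}, rate: 1.0}
- {reactants: {S2: 1}, products: {}, rate: 0.025}
event: {species: S2, theta: 65, T: 100}
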