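name: futile_cycle
species:
- {name: S1, initial: 1}
- {name: S2, initial: 50}
- {name: S3, initial: 0}
- {name: S4, initial: 1}
- {name: S5, initial: 50}
- {name: S6, initial: 0}
reactions:
- {reactants: {S1: 1, S2: 1}, products: {S3: 1}, rate: 1.0}
- {reactants: {S3: 1}, products: {S1: 1, S2: 1}, rate: 1.0}
- {reactants: {S3: 1}, products: {S1: 1, S5: 1}, rate: 0.1}
- {reactants: {S4: 1, S5: 1}, products: {S6: 1}, rate: 1.0}
- {reactants: {S6: 1}, products: {S4: 1, S5: 1}, rate: 1.0}
- {reactants: {S6: 1}, products: {S4: 1, S2: 1}, rate: 0.1}
event: {species: S5, theta: 40, T: 100}
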