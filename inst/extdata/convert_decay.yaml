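name: convert_decay
species:
- {name: S1, initial: 40}
- {name: S2, initial: 40}
- {name: S3, initial: 1}
reactions:
- {reactants: {S1: 1}, products: {S2: 1}, rate: 0.1}
- {reactants: {S2: 1}, products: {}, rate: 0.1}
- {reactants: {S3: 1}, products: {S3: 1, S1: 1}, rate: 8.0}
- {reactants: {S1: 1}, products: {}, rate: 0.1}
event: {species: S2, theta: 65, T: 10}
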