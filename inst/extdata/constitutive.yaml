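# Constitutive single-gene reporter: burst frequency a = km/gx = 4,
# burst size b = kx/gm = 10, stationary protein mean 40.
n_genes: 1
names: [reporter]
topology:
- [0]
genes:
- {km: 4.0, kx: 100.0, gm: 10.0, gx: 1.0, eps: 0.0}
edges: []
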