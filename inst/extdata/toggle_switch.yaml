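# Mutual-repression toggle switch: bimodal stationary distribution with
# anticorrelated high/low protein states.
n_genes: 2
names: [lacI, tetR]
topology:
- [0, -1]
- [-1, 0]
genes:
- {km: 4.0, kx: 50.0, gm: 10.0, gx: 1.0, eps: 0.02}
- {km: 4.0, kx: 50.0, gm: 10.0, gx: 1.0, eps: 0.02}
edges:
- {i: 1, j: 2, K: 6.0, n: 3.0}
- {i: 2, j: 1, K: 6.0, n: 3.0}
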