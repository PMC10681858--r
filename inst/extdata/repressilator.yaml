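# Three-gene repression ring (protein j represses gene j+1, cyclic):
# noisy oscillator with a clear positive-lag autocorrelation peak.
n_genes: 3
names: [lacI, tetR, cI]
topology:
- [0, 0, -1]
- [-1, 0, 0]
- [0, -1, 0]
genes:
- {km: 8.0, kx: 100.0, gm: 10.0, gx: 1.0, eps: 0.0}
- {km: 8.0, kx: 100.0, gm: 10.0, gx: 1.0, eps: 0.0}
- {km: 8.0, kx: 100.0, gm: 10.0, gx: 1.0, eps: 0.0}
edges:
- {i: 1, j: 3, K: 20.0, n: 4.0}
- {i: 2, j: 1, K: 20.0, n: 4.0}
- {i: 3, j: 2, K: 20.0, n: 4.0}
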