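# Shared helpers for the test suite. Circuits built in code, no fixtures on
# disk beyond the packaged YAML configs.

# single unregulated gene with explicit rates (used where tests reference
# the analytic means km/gm and km*kx/(gm*gx) directly)
plain_gene <- function(km = 10, kx = 5, gm = 5, gx = 1) {
  gene_circuit(matrix(0L, 1L, 1L), km = km, kx = kx, gm = gm, gx = gx)
}

# a single self-activating gene with zero leakage: the all-zero state is
# absorbing (promoter activity 0 with no protein around)
absorbing_gene <- function() {
  gene_circuit(matrix(1L, 1L, 1L), km = 5, kx = 5, gm = 1, gx = 1,
               K = matrix(10), n_hill = matrix(2))
}

trapz <- function(y, x) sum(y * stochcirc:::trapz_weights(x))

# discretized, normalized Gamma density on a grid line
gamma_on_grid <- function(nodes, shape, scale) {
  v <- dgamma(nodes, shape = shape, scale = scale)
  v / trapz(v, nodes)
}

normalize_hist <- function(v) {
  v[v < 0] <- 0
  v / sum(v)
}
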