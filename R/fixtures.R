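#' Bundled example circuits
#'
#' Three reference circuits exercising the package end to end, with kinetic
#' parameters chosen inside the bursty expression regime (fast mRNA
#' turnover, `gm/gx = 10`, burst sizes 5-10) where the protein-only PIDE is
#' an accurate reduction of the full chemical master equation:
#'
#' * `"constitutive"` — one unregulated gene (`km = 4`, `kx = 100`,
#'   `gm = 10`, `gx = 1`): burst frequency `a = km/gx = 4`, burst size
#'   `b = kx/gm = 10`, stationary protein mean 40. Its PIDE stationary law
#'   is the Gamma density with shape `a` and scale `b`.
#' * `"toggle_switch"` — two mutually repressing genes (cooperativity 3,
#'   threshold 6, leakage 0.02, `km = 4`, `kx = 50`, `gm = 10`, `gx = 1`):
#'   bimodal stationary distribution with anticorrelated high/low states.
#' * `"repressilator"` — three genes in a repression ring (protein `i`
#'   represses gene `i + 1`; cooperativity 4, threshold 20, no leakage,
#'   `km = 8`, `kx = 100`, `gm = 10`, `gx = 1`):
#'   noisy oscillations with a clear positive-lag autocorrelation peak.
#'
#' The same circuits ship as YAML configs under
#' `system.file("extdata", package = "stochcirc")`.
#'
#' @param name fixture name.
#' @return A validated `gene_circuit`.
#' @export
fixture_circuit <- function(name = c("constitutive", "toggle_switch",
                                     "repressilator")) {
  name <- match.arg(name)
  switch(name,
    constitutive = gene_circuit(
      topology = matrix(0L, 1L, 1L),
      km = 4, kx = 100, gm = 10, gx = 1, eps = 0,
      names = "reporter"),
    toggle_switch = gene_circuit(
      topology = matrix(c(0L, -1L, -1L, 0L), 2L, 2L, byrow = TRUE),
      km = 4, kx = 50, gm = 10, gx = 1, eps = 0.02,
      K = matrix(c(NA, 6, 6, NA), 2L, 2L, byrow = TRUE),
      n_hill = matrix(c(NA, 3, 3, NA), 2L, 2L, byrow = TRUE),
      names = c("lacI", "tetR")),
    repressilator = {
      T0 <- matrix(0L, 3L, 3L)
      K <- matrix(NA_real_, 3L, 3L)
      nh <- matrix(NA_real_, 3L, 3L)
      for (j in 1:3) {
        i <- j %% 3L + 1L  # protein j represses gene j+1 (cyclic)
        T0[i, j] <- -1L
        K[i, j] <- 20
        nh[i, j] <- 4
      }
      gene_circuit(T0, km = 8, kx = 100, gm = 10, gx = 1, eps = 0,
                   K = K, n_hill = nh,
                   names = c("lacI", "tetR", "cI"))
    })
}

#' Generate synthetic histogram time-series data
#'
#' Draws an SSA ensemble of the (optionally perturbed) circuit at the
#' requested times and bins the protein counts into normalized histograms,
#' emulating distribution-valued flow-cytometry-style observations. The
#' perturbed circuit is returned as the ground-truth record for parameter
#' recovery experiments. Deterministic given `seed`.
#'
#' @param circuit a `gene_circuit`.
#' @param t_points sampling times (nonempty).
#' @param n_samples ensemble size (>= 100).
#' @param edges bin edges (vector for 1-D, list of vectors for 2-D joints).
#' @param seed integer master seed (drives both the parameter perturbation
#'   and the SSA ensemble).
#' @param genes histogram axes (gene indices, length 1 or 2).
#' @param perturbation multiplicative half-width: each rate constant of the
#'   circuit is scaled by an independent factor drawn uniformly from
#'   `[1 - perturbation, 1 + perturbation]` before simulation (0 = none).
#' @return A list of class `pseudo_data`: `dataset` (a
#'   `histogram_dataset`), `truth` (the perturbed `gene_circuit` actually
#'   simulated) and `factors` (the perturbation factors applied).
#' @export
make_pseudo_data <- function(circuit, t_points, n_samples, edges, seed,
                             genes = 1L, perturbation = 0) {
  validate_circuit(circuit)
  if (length(t_points) == 0L) stop("t_points must be nonempty")
  if (n_samples < 100L) stop("n_samples must be >= 100")
  truth <- circuit
  factors <- NULL
  if (perturbation > 0) {
    set.seed(as.integer(seed))
    fields <- c("km", "kx", "gm", "gx")
    factors <- lapply(fields, function(f)
      stats::runif(circuit$n_genes, 1 - perturbation, 1 + perturbation))
    names(factors) <- fields
    for (f in fields) truth[[f]] <- truth[[f]] * factors[[f]]
    truth <- validate_circuit(truth)
  }
  ens <- ssa_ensemble(truth, t_points, n_runs = n_samples, seed = seed)
  if (!is.list(edges)) edges <- rep(list(edges), length(genes))
  values <- lapply(seq_along(t_points), function(k)
    ensemble_histogram(ens, edges, time_index = k, genes = genes)$values)
  dataset <- histogram_dataset(t_points, values, edges, genes = genes,
                               counts = rep(n_samples, length(t_points)))
  structure(list(dataset = dataset, truth = truth, factors = factors,
                 seed = seed),
            class = "pseudo_data")
}
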