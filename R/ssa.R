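#' Exact stochastic simulation of a gene circuit
#'
#' Gillespie direct-method simulation of the `4 * n_genes` reaction network
#' (transcription with Hill-regulated propensity, translation, and first-order
#' degradation of mRNA and protein). Waiting times are exponential in the
#' total propensity and reactions are chosen proportionally to their
#' propensities, so trajectories are exact samples of the chemical master
#' equation. The simulation is bitwise reproducible for a given
#' `(circuit, seed, stream)`.
#'
#' With `record = "grid"` the state is recorded on `t_grid` by
#' piecewise-constant interpolation (state at the largest event time <= t),
#' which avoids storing the full event list. `record = "events"` keeps every
#' event (times, reaction indices, states) up to `max_events`.
#'
#' @param circuit a `gene_circuit`.
#' @param t_end final time (> start time).
#' @param seed integer master seed.
#' @param t_grid recording times for `record = "grid"`; default
#'   `seq(0, t_end, length.out = n_record)`.
#' @param n_record number of uniform recording times when `t_grid` is `NULL`.
#' @param initial optional list with integer vectors `mrna`, `protein` and
#'   scalar `t` (defaults: all zeros at `t = 0`).
#' @param record `"grid"` (default) or `"events"`.
#' @param stream substream index (used internally by ensembles).
#' @param max_events guard for `record = "events"`.
#' @return An object of class `ssa_trajectory`: list with `times`, `mrna`
#'   and `protein` matrices (rows = times), the `record` mode, `seed`, and
#'   for event recording also `reaction` indices.
#' @examples
#' circ <- fixture_circuit("constitutive")
#' tr <- ssa_simulate(circ, t_end = 5, seed = 1)
#' tail(tr$protein)
#' @export
ssa_simulate <- function(circuit, t_end, seed, t_grid = NULL, n_record = 201L,
                         initial = NULL, record = c("grid", "events"),
                         stream = 0L, max_events = 2e7) {
  record <- match.arg(record)
  validate_circuit(circuit)
  init <- ssa_initial(circuit, initial)
  if (t_end <= init$t) stop("t_end must exceed the initial time")
  seed <- as.numeric(seed)
  if (record == "grid") {
    if (is.null(t_grid)) t_grid <- seq(init$t, t_end, length.out = n_record)
    if (is.unsorted(t_grid)) stop("t_grid must be nondecreasing")
    out <- .ssa_run_cpp(circuit$topology, circuit$km, circuit$kx, circuit$gm,
                        circuit$gx, circuit$eps, circuit$K, circuit$n_hill,
                        init$mrna, init$protein, init$t, as.numeric(t_grid),
                        seed, as.numeric(stream))
    structure(list(times = as.numeric(t_grid), mrna = out$mrna,
                   protein = out$protein, n_events = out$n_events,
                   record = "grid", seed = seed),
              class = "ssa_trajectory")
  } else {
    out <- .ssa_events_cpp(circuit$topology, circuit$km, circuit$kx,
                           circuit$gm, circuit$gx, circuit$eps, circuit$K,
                           circuit$n_hill, init$mrna, init$protein, init$t,
                           t_end, seed, as.numeric(stream), max_events)
    structure(list(times = out$times, reaction = out$reaction,
                   mrna = out$mrna, protein = out$protein,
                   initial = init, t_end = t_end,
                   record = "events", seed = seed),
              class = "ssa_trajectory")
  }
}

ssa_initial <- function(circuit, initial) {
  n <- circuit$n_genes
  init <- list(mrna = rep(0L, n), protein = rep(0L, n), t = 0)
  if (!is.null(initial)) {
    for (f in names(initial)) init[[f]] <- initial[[f]]
  }
  init$mrna <- as.integer(init$mrna)
  init$protein <- as.integer(init$protein)
  if (any(init$mrna < 0) || any(init$protein < 0))
    stop("initial copy numbers must be nonnegative")
  init
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("<ssa_trajectory> ", ncol(x$protein), " gene(s), ",
      length(x$times), " records (", x$record, "), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Ensemble of independent SSA runs
#'
#' Runs `n_runs` independent trajectories with per-run RNG streams derived
#' deterministically from the master seed (counter-based splitting), and
#' records protein and mRNA copy numbers at each requested time. The result
#' does not depend on execution order.
#'
#' @param circuit a `gene_circuit`.
#' @param t_points nondecreasing sampling times.
#' @param n_runs number of runs (>= 1).
#' @param seed integer master seed.
#' @param initial as in [ssa_simulate()].
#' @return An object of class `ssa_ensemble` with arrays `protein` and
#'   `mrna` of dimension `n_runs x n_genes x n_times`.
#' @export
ssa_ensemble <- function(circuit, t_points, n_runs, seed, initial = NULL) {
  validate_circuit(circuit)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (is.unsorted(t_points)) stop("t_points must be nondecreasing")
  init <- ssa_initial(circuit, initial)
  out <- .ssa_ensemble_cpp(circuit$topology, circuit$km, circuit$kx,
                           circuit$gm, circuit$gx, circuit$eps, circuit$K,
                           circuit$n_hill, init$mrna, init$protein, init$t,
                           as.numeric(t_points), as.integer(n_runs),
                           as.numeric(seed))
  structure(list(t_points = as.numeric(t_points), n_runs = as.integer(n_runs),
                 protein = out$protein, mrna = out$mrna,
                 seed = as.numeric(seed)),
            class = "ssa_ensemble")
}

#' Empirical histograms from an SSA ensemble
#'
#' Bins the protein counts of an ensemble at one sampling time into a
#' normalized histogram: a 1-D marginal for a single gene or a joint
#' histogram over two genes. Samples above the top edge are clamped into the
#' last bin so every histogram sums to exactly 1.
#'
#' @param ensemble an `ssa_ensemble`.
#' @param edges numeric vector of strictly increasing bin edges (first edge
#'   must be <= 0 to include zero counts), or a list of one vector per gene
#'   in `genes`.
#' @param time_index index into the ensemble's `t_points` (default: last).
#' @param genes gene indices (length 1 or 2).
#' @return An `ensemble_histogram`: list with `values` (array summing to 1),
#'   `edges` (list), `t`, `genes` and `n_runs`.
#' @export
ensemble_histogram <- function(ensemble, edges, time_index = NULL,
                               genes = 1L) {
  if (is.null(time_index)) time_index <- length(ensemble$t_points)
  if (!is.list(edges)) edges <- rep(list(edges), length(genes))
  stopifnot(length(edges) == length(genes))
  for (e in edges) {
    if (is.unsorted(e, strictly = TRUE)) stop("bin edges must be strictly increasing")
  }
  idx <- lapply(seq_along(genes), function(k) {
    xs <- ensemble$protein[, genes[k], time_index]
    e <- edges[[k]]
    i <- findInterval(xs, e, rightmost.closed = TRUE, left.open = FALSE)
    if (any(i == 0L)) stop("samples below the first bin edge")
    pmin(i, length(e) - 1L)  # clamp overflow into the last bin
  })
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  counts <- array(0, nb)
  flat <- idx[[1L]]
  if (length(genes) == 2L) flat <- flat + nb[1L] * (idx[[2L]] - 1L)
  tab <- tabulate(flat, nbins = prod(nb))
  counts[] <- tab
  structure(list(values = counts / ensemble$n_runs, edges = edges,
                 t = ensemble$t_points[time_index], genes = genes,
                 n_runs = ensemble$n_runs),
            class = "ensemble_histogram")
}

#' Write a trajectory to delimited text
#'
#' Columns: `time, mRNA_1..n, X_1..n`, tab-separated with a comment header.
#' @param trajectory an `ssa_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  n <- ncol(trajectory$protein)
  df <- data.frame(time = trajectory$times, trajectory$mrna,
                   trajectory$protein)
  names(df) <- c("time", paste0("mRNA_", seq_len(n)), paste0("X_", seq_len(n)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# stochcirc trajectory (copy numbers, molecules; time in model units)",
               paste0("# seed: ", trajectory$seed)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
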