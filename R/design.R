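#' Normalized autocorrelation of a series
#'
#' \eqn{R(\tau) = \sum_t (x_t-\bar x)(x_{t+\tau}-\bar x) / \sum_t (x_t-\bar x)^2}
#' for lags `0..max_lag` (so `R(0) = 1`). The default FFT estimator and the
#' direct double-loop estimator compute the identical quantity (they agree
#' to numerical roundoff); the direct form serves as an independent oracle
#' in tests.
#'
#' @param x numeric series.
#' @param max_lag largest lag (< `length(x)`).
#' @param method `"fft"` (default) or `"direct"`.
#' @return Numeric vector of length `max_lag + 1` (lags `0..max_lag`).
#' @export
autocorr <- function(x, max_lag, method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("constant series has undefined autocorrelation")
  if (method == "direct") {
    vapply(0:max_lag, function(k)
      sum(xc[seq_len(n - k)] * xc[(k + 1L):n]) / denom, numeric(1L))
  } else {
    m <- stats::nextn(2L * n)
    a <- stats::fft(c(xc, rep(0, m - n)))
    s <- Re(stats::fft(Mod(a)^2, inverse = TRUE)) / m
    s[1:(max_lag + 1L)] / s[1L]
  }
}

#' Second peak of the autocorrelation function
#'
#' Discards `burn_in` samples, computes the normalized autocorrelation and
#' returns the height and lag of its first strict local maximum at positive
#' lag (the trivial `R(0) = 1` peak being the first). A candidate counts as
#' a peak only if it rises at least `prominence` above the minimum reached
#' between lag 0 and the candidate, which skips noise wiggles. Near-constant
#' series return height 0 with `degenerate = TRUE`.
#'
#' The peak height measures the coherence of noisy oscillations: 1 for a
#' pure periodic signal, near 0 for white-noise-like dynamics.
#'
#' @param x protein copy-number series sampled on a uniform grid.
#' @param burn_in samples to discard from the start.
#' @param max_lag largest lag examined (samples).
#' @param prominence minimum rise above the preceding trough.
#' @return List with `height`, `lag` (samples, `NA` if no peak) and
#'   `degenerate`.
#' @export
autocorr_second_peak <- function(x, burn_in = 0L, max_lag = NULL,
                                 prominence = 0.01) {
  x <- x[(burn_in + 1L):length(x)]
  n <- length(x)
  if (is.null(max_lag)) max_lag <- floor(n / 4)
  if (n < 2L * max_lag + 1L)
    stop("series too short: need length > burn_in + 2 * max_lag")
  if (stats::var(x) == 0)
    return(list(height = 0, lag = NA_integer_, degenerate = TRUE))
  R <- autocorr(x, max_lag)
  for (k in 2:max_lag) {        # lag index k corresponds to lag k - 1
    if (k == max_lag + 1L) break
    Rk <- R[k]
    if (Rk > R[k - 1L] && k < length(R) && Rk > R[k + 1L]) {
      trough <- min(R[1:k])
      if (Rk - trough >= prominence)
        return(list(height = Rk, lag = k - 1L, degenerate = FALSE))
    }
  }
  list(height = 0, lag = NA_integer_, degenerate = FALSE)
}

# ---------------------------------------------------------------------------

#' Define an automated design problem
#'
#' Encodes a circuit family as one mixed decision vector: free topology
#' entries (integers in \{-1, 0, +1\}), free cooperativities (integers in
#' `[1, n_max]`), and free real parameters with bounds, everything else
#' fixed. The decision vector is ordered: topology slots, cooperativity
#' slots, real slots.
#'
#' @param base_circuit `gene_circuit` supplying every fixed value (its
#'   topology entries at free slots are ignored).
#' @param topology_free 2-column matrix (or `data.frame`) of `[i, j]` index
#'   pairs whose topology entries are free; `NULL` for none.
#' @param coop_free index pairs whose cooperativities are free integers.
#' @param coop_bounds integer bounds for free cooperativities (default
#'   `c(1, 4)`).
#' @param real_free list of free real parameters,
#'   `list(name, lower, upper, log)` as in [calibration_problem()].
#' @param edge_defaults list with `K` and `n` giving the regulation
#'   threshold and cooperativity assigned to an edge the search switches on
#'   at a position where the base circuit has none.
#' @param objective an objective function of a `gene_circuit` returning a
#'   scalar cost (lower is better); see `objective_*` helpers.
#' @param budget optimizer evaluation budget.
#' @param seed integer seed (also fixes any stochastic objective).
#' @param memoize cache objective values per decision vector (objectives are
#'   pure functions of the decision vector, so repeated evaluations are
#'   served from the cache; they still count toward the budget).
#' @return An object of class `design_problem`.
#' @export
design_problem <- function(base_circuit, objective, topology_free = NULL,
                           coop_free = NULL, coop_bounds = c(1L, 4L),
                           real_free = list(), edge_defaults = list(K = 10, n = 2),
                           budget = 200L, seed = 1L, memoize = TRUE) {
  validate_circuit(base_circuit)
  as_pairs <- function(m) {
    if (is.null(m)) return(matrix(integer(0), 0L, 2L))
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  }
  topology_free <- as_pairs(topology_free)
  coop_free <- as_pairs(coop_free)
  real_free <- lapply(real_free, function(f) {
    if (is.null(f$log)) f$log <- grepl("^(km|kx|gm|gx|K)", f$name)
    f
  })
  structure(list(base_circuit = base_circuit, objective = objective,
                 topology_free = topology_free, coop_free = coop_free,
                 coop_bounds = as.integer(coop_bounds),
                 real_free = real_free, edge_defaults = edge_defaults,
                 budget = as.integer(budget), seed = as.integer(seed),
                 memoize = isTRUE(memoize)),
            class = "design_problem")
}

design_bounds <- function(problem) {
  nt <- nrow(problem$topology_free)
  nc <- nrow(problem$coop_free)
  rb <- theta_bounds(list(free = problem$real_free))
  list(lower = c(rep(-1, nt), rep(problem$coop_bounds[1L], nc), rb$lower),
       upper = c(rep(1, nt), rep(problem$coop_bounds[2L], nc), rb$upper),
       integer = seq_len(nt + nc))
}

#' Decode a decision vector into a circuit
#'
#' Free topology slots take the integer values of `z`; switching an entry on
#' where the base circuit has no edge attaches the `edge_defaults`
#' regulation parameters, and switching one off drops its `(K, n)` pair.
#' Free cooperativities apply only to edges that end up present. Real slots
#' are decoded as in calibration (log slots exponentiated). All-fixed
#' problems ignore `z` and return the base circuit.
#'
#' @param problem a `design_problem`.
#' @param z decision vector within bounds.
#' @return A validated `gene_circuit`.
#' @export
decode_design <- function(problem, z) {
  b <- design_bounds(problem)
  if (length(z) != length(b$lower))
    stop("decision vector has length ", length(z), ", expected ",
         length(b$lower))
  if (any(z < b$lower - 1e-9) || any(z > b$upper + 1e-9))
    stop("decision vector outside bounds")
  circuit <- problem$base_circuit
  nt <- nrow(problem$topology_free)
  nc <- nrow(problem$coop_free)
  for (r in seq_len(nt)) {
    i <- problem$topology_free[r, 1L]; j <- problem$topology_free[r, 2L]
    t_new <- as.integer(round(z[r]))
    circuit$topology[i, j] <- t_new
    if (t_new == 0L) {
      circuit$K[i, j] <- NA_real_
      circuit$n_hill[i, j] <- NA_real_
    } else if (is.na(circuit$K[i, j])) {
      circuit$K[i, j] <- problem$edge_defaults$K
      circuit$n_hill[i, j] <- problem$edge_defaults$n
    }
  }
  for (r in seq_len(nc)) {
    i <- problem$coop_free[r, 1L]; j <- problem$coop_free[r, 2L]
    if (circuit$topology[i, j] != 0L)
      circuit$n_hill[i, j] <- round(z[nt + r])
  }
  for (k in seq_along(problem$real_free)) {
    f <- problem$real_free[[k]]
    value <- if (f$log) exp(z[nt + nc + k]) else z[nt + nc + k]
    circuit <- param_set(circuit, f$name, value)
  }
  validate_circuit(circuit)
}

#' Encode a circuit into a decision vector
#'
#' Inverse of [decode_design()] on the free slots (fixed slots do not appear
#' in the vector); `decode_design(problem, encode_design(problem, c))`
#' reproduces `c` on every free slot.
#'
#' @param problem a `design_problem`.
#' @param circuit a `gene_circuit` compatible with the problem.
#' @return Numeric decision vector.
#' @export
encode_design <- function(problem, circuit) {
  nt <- nrow(problem$topology_free)
  z_top <- vapply(seq_len(nt), function(r)
    as.numeric(circuit$topology[problem$topology_free[r, 1L],
                                problem$topology_free[r, 2L]]), numeric(1L))
  z_coop <- vapply(seq_len(nrow(problem$coop_free)), function(r) {
    i <- problem$coop_free[r, 1L]; j <- problem$coop_free[r, 2L]
    v <- circuit$n_hill[i, j]
    if (is.na(v)) problem$coop_bounds[1L] else v
  }, numeric(1L))
  z_real <- vapply(problem$real_free, function(f) {
    v <- param_get(circuit, f$name)
    if (f$log) log(v) else v
  }, numeric(1L))
  c(z_top, z_coop, z_real)
}

# ---------------------------------------------------------------------------
# Objectives. Each returns a scalar cost (lower is better) and is a pure
# function of (circuit, spec); stochastic dynamics use a fixed seed.

#' Target stationary distribution objective
#'
#' KL divergence from a target histogram to the circuit's stationary
#' distribution aggregated onto the target's bins. Non-convergent stationary
#' solves return the penalty value 1e6.
#'
#' @param circuit a `gene_circuit`.
#' @param target_hist target histogram array (normalized).
#' @param edges list of bin-edge vectors matching `target_hist`.
#' @param genes gene indices the histogram axes refer to.
#' @param solver_opts list: `n_points`, `safety_factor`, `dt`, `tol` for the
#'   stationary solve.
#' @return Nonnegative scalar cost.
#' @export
objective_target_stationary <- function(circuit, target_hist, edges,
                                        genes = seq_along(edges),
                                        solver_opts = list()) {
  st <- design_stationary(circuit, solver_opts)
  if (is.null(st)) return(1e6)
  if (length(genes) == 1L && st$grid$n_genes > 1L)
    st <- field_marginal(st, genes)
  masses <- bin_field(st, edges)
  masses[masses < 0] <- 0
  kl_divergence(target_hist, masses / sum(masses))
}

#' Bimodality objective
#'
#' Cost of deviating from a prescribed two-state behavior:
#' `sum_domains |mass(domain) - target|` plus a hinge penalty
#' `max(0, min_mode_distance - d)` where `d` is the distance between the two
#' largest strict local maxima of the stationary field. Fields with fewer
#' than two modes receive the full hinge penalty.
#'
#' @param circuit a `gene_circuit`.
#' @param domains list of two disjoint rectangular domains, each
#'   `list(lower =, upper =)` in protein units (vectors over genes).
#' @param target_masses probability targets for the two domains (sum <= 1).
#' @param min_mode_distance required separation between the two main modes
#'   (molecules, Euclidean).
#' @param solver_opts stationary solver settings (see
#'   [objective_target_stationary()]).
#' @return Nonnegative scalar cost.
#' @export
objective_bimodality <- function(circuit, domains, target_masses,
                                 min_mode_distance = 0, solver_opts = list()) {
  stopifnot(length(domains) == 2L, length(target_masses) == 2L,
            sum(target_masses) <= 1 + 1e-12)
  st <- design_stationary(circuit, solver_opts)
  if (is.null(st)) return(1e6)
  cost <- 0
  for (k in 1:2) {
    mass <- domain_mass(st, domains[[k]])
    cost <- cost + abs(mass - target_masses[k])
  }
  if (min_mode_distance > 0) {
    modes <- find_modes(st, min_value = 1e-12)
    d <- if (nrow(modes) >= 2L) {
      nd <- st$grid$n_genes
      xs <- as.matrix(modes[1:2, paste0("x", seq_len(nd)), drop = FALSE])
      sqrt(sum((xs[1L, ] - xs[2L, ])^2))
    } else 0
    cost <- cost + max(0, min_mode_distance - d)
  }
  cost
}

# Probability mass of the field's interpolant inside a rectangle.
domain_mass <- function(field, domain) {
  nd <- field$grid$n_genes
  wks <- lapply(seq_len(nd), function(d)
    hat_integral(field$grid$nodes[[d]], field$grid$h[d],
                 domain$lower[d], domain$upper[d]))
  W <- wks[[1L]]
  if (nd > 1L) for (d in 2L:nd) W <- outer(W, wks[[d]])
  sum(field$P * array(W, dim(field$P) %||% length(field$P)))
}

# Stationary solve with penalty semantics for design objectives.
design_stationary <- function(circuit, solver_opts) {
  opts <- utils::modifyList(
    list(n_points = 48L, safety_factor = 4, dt = NULL, tol = 5e-4,
         max_iter = 200000L),
    solver_opts)
  tryCatch({
    grid <- make_grid(circuit, n_points = opts$n_points,
                      safety_factor = opts$safety_factor)
    pide_stationary(circuit, grid = grid, dt = opts$dt, tol = opts$tol,
                    max_iter = opts$max_iter)
  }, error = function(e) NULL)
}

#' Oscillation-robustness objective
#'
#' Simulates one SSA protein trajectory with a fixed seed and returns minus
#' the height of the second autocorrelation peak, so maximally robust
#' oscillators score most negative. Degenerate (constant) trajectories get a
#' penalty of +1.
#'
#' @param circuit a `gene_circuit`.
#' @param gene protein whose dynamics are scored.
#' @param t_sample sampling interval of the recorded series.
#' @param n_samples recorded series length (default 20000).
#' @param burn_in samples discarded before the autocorrelation (default 2000).
#' @param seed fixed seed making the objective deterministic.
#' @param max_lag autocorrelation window (samples).
#' @return Scalar cost in `[-1, 1]`.
#' @export
objective_oscillation <- function(circuit, gene = 1L, t_sample = 0.2,
                                  n_samples = 20000L, burn_in = 2000L,
                                  seed = 1L, max_lag = NULL) {
  t_grid <- seq(0, by = t_sample, length.out = n_samples + burn_in)
  tr <- tryCatch(
    ssa_simulate(circuit, t_end = max(t_grid), t_grid = t_grid, seed = seed),
    error = function(e) NULL)
  if (is.null(tr)) return(1)
  pk <- autocorr_second_peak(tr$protein[, gene], burn_in = burn_in,
                             max_lag = max_lag %||% floor(n_samples / 5))
  if (isTRUE(pk$degenerate)) return(1)
  -pk$height
}

#' Target-dynamics objective
#'
#' Summed KL divergence between target histograms at stated times and the
#' solved PIDE distribution aggregated to the same bins (shares its
#' machinery with the calibration cost).
#'
#' @param circuit a `gene_circuit`.
#' @param dataset a `histogram_dataset` holding the target distributions.
#' @param solver_opts PIDE settings as in [calibration_problem()].
#' @return Nonnegative scalar cost.
#' @export
objective_target_dynamics <- function(circuit, dataset, solver_opts = list()) {
  problem <- list(dataset = dataset, simulator = "pide",
                  solver_opts = utils::modifyList(
                    list(n_points = 64L, safety_factor = 4, dt = NULL),
                    solver_opts))
  model <- tryCatch(model_histograms(problem, circuit),
                    error = function(e) NULL)
  if (is.null(model)) return(1e6)
  cost <- sum(vapply(seq_along(dataset$times), function(k)
    kl_divergence(dataset$values[[k]], model[[k]]), numeric(1L)))
  if (!is.finite(cost)) 1e6 else cost
}

#' Solve a design problem
#'
#' Minimizes the objective over the mixed decision vector with
#' [minlp_minimize()] and decodes the best solution. Deterministic given the
#' problem seed. With memoization enabled (default), repeated evaluations of
#' the same decision vector are served from a cache (objectives are pure),
#' though every evaluation still counts against the budget.
#'
#' @param problem a `design_problem`.
#' @return A list of class `design_result`: the `optim_result`, the decoded
#'   best `circuit`, and the best objective `value`.
#' @export
design_circuit <- function(problem) {
  b <- design_bounds(problem)
  if (length(b$lower) == 0L) {
    value <- problem$objective(problem$base_circuit)
    return(structure(list(result = NULL, circuit = problem$base_circuit,
                          value = value, problem = problem),
                     class = "design_result"))
  }
  cache <- new.env(parent = emptyenv())
  fn <- function(z) {
    circuit <- decode_design(problem, z)
    if (problem$memoize) {
      key <- paste(signif(z, 12), collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- problem$objective(circuit)
      cache[[key]] <- val
      val
    } else {
      problem$objective(circuit)
    }
  }
  res <- minlp_minimize(fn, lower = b$lower, upper = b$upper,
                        integer = b$integer, budget = problem$budget,
                        seed = problem$seed)
  structure(list(result = res, circuit = decode_design(problem, res$par),
                 value = res$value, problem = problem),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> objective ", format(x$value), "\n", sep = "")
  print(x$circuit)
  invisible(x)
}

#' Enumerate all topologies of a design problem
#'
#' Brute-force oracle for small problems: evaluates the objective for every
#' assignment of the free topology slots (3^n combinations), holding
#' cooperativity and real slots at the base circuit's encoded values.
#'
#' @param problem a `design_problem` with free topology slots only (or whose
#'   other free slots should stay at their base values).
#' @return Data frame of decision vectors and objective values, sorted by
#'   cost; best row first.
#' @export
enumerate_topologies <- function(problem) {
  nt <- nrow(problem$topology_free)
  if (nt == 0L) stop("problem has no free topology slots")
  z0 <- encode_design(problem, problem$base_circuit)
  grids <- rep(list(c(-1, 0, 1)), nt)
  combos <- as.matrix(expand.grid(grids))
  values <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    z <- z0
    z[seq_len(nt)] <- combos[r, ]
    values[r] <- problem$objective(decode_design(problem, z))
  }
  out <- data.frame(combos, value = values)
  names(out) <- c(paste0("z", seq_len(nt)), "value")
  out[order(out$value), , drop = FALSE]
}
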