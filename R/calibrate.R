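#' Histogram time-series dataset
#'
#' Distribution-valued observations for calibration: at each sampling time a
#' normalized histogram of protein levels over a fixed bin structure (1-D
#' marginal of one gene or 2-D joint of two genes). The same bin edges apply
#' at every time.
#'
#' @param times numeric sampling times.
#' @param values list of histogram arrays, one per time, each summing to 1
#'   (tolerance 1e-9).
#' @param edges list of per-axis bin-edge vectors (a single vector is
#'   promoted to a 1-axis list).
#' @param genes gene indices the axes correspond to (length 1 or 2).
#' @param counts optional per-time sample counts.
#' @return An object of class `histogram_dataset`.
#' @export
histogram_dataset <- function(times, values, edges, genes = 1L,
                              counts = NULL) {
  if (!is.list(edges)) edges <- list(edges)
  if (length(edges) != length(genes))
    stop("need one edge vector per histogram axis")
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  if (length(values) != length(times))
    stop("need one histogram per sampling time")
  values <- lapply(values, function(v) {
    v <- array(v, nb)
    if (abs(sum(v) - 1) > 1e-9)
      stop("each histogram must sum to 1 (tolerance 1e-9)")
    if (any(v < 0)) stop("histogram masses must be nonnegative")
    v
  })
  for (e in edges)
    if (is.unsorted(e, strictly = TRUE))
      stop("bin edges must be strictly increasing")
  structure(list(times = as.numeric(times), values = values, edges = edges,
                 genes = as.integer(genes), counts = counts),
            class = "histogram_dataset")
}

#' Kullback-Leibler divergence between two histograms
#'
#' \eqn{D(p\,\|\,q) = \sum_{k: p_k>0} p_k \log(p_k/q_k)} in nats, with the
#' model histogram floored at `floor_mass` per bin (then renormalized) so
#' empty model bins do not produce infinities. Asymmetric: the data
#' histogram is always the first argument in calibration costs.
#'
#' @param p,q histograms (arrays of identical dimension, each summing to 1
#'   up to small numerical tolerance).
#' @param floor_mass pseudo-mass floor applied to `q`.
#' @return Nonnegative scalar; 0 iff `p == q` (up to flooring).
#' @export
kl_divergence <- function(p, q, floor_mass = 1e-12) {
  dp <- as.integer(dim(p) %||% length(p))
  dq <- as.integer(dim(q) %||% length(q))
  if (!identical(dp, dq))
    stop("histograms have mismatched bin structure")
  p <- as.numeric(p); q <- as.numeric(q)
  if (any(p < 0) || any(q < 0)) stop("histogram masses must be nonnegative")
  q <- pmax(q, floor_mass)
  q <- q / sum(q)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

#' Define a calibration problem
#'
#' Fixes the circuit topology and a template parameter set, declares which
#' parameters are free (with bounds and log-scale flags), and attaches the
#' observed histogram dataset. Free parameters are addressed by name:
#' `"km1"`, `"kx2"`, `"gm1"`, `"gx1"`, `"eps1"` for per-gene constants and
#' `"K_1_2"` / `"n_1_2"` for the edge of protein 2 acting on gene 1. Rate and
#' threshold parameters default to log-scale search (they span decades);
#' cooperativities and leakages are searched linearly.
#'
#' @param circuit template `gene_circuit` (supplies topology and all fixed
#'   parameter values).
#' @param free list of free-parameter specs: each
#'   `list(name, lower, upper, log)` (`log` defaults to `TRUE` for
#'   km/kx/gm/gx/K, `FALSE` otherwise).
#' @param dataset a `histogram_dataset`.
#' @param simulator `"pide"` (default) or `"ssa"` ensemble backend.
#' @param budget optimizer evaluation budget.
#' @param seed integer seed.
#' @param solver_opts list of backend settings: for the PIDE backend
#'   `n_points`, `safety_factor`, `dt`; for the SSA backend `n_runs`.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(circuit, free, dataset,
                                simulator = c("pide", "ssa"),
                                budget = 200L, seed = 1L,
                                solver_opts = list()) {
  simulator <- match.arg(simulator)
  validate_circuit(circuit)
  if (!inherits(dataset, "histogram_dataset"))
    stop("dataset must be a histogram_dataset")
  if (length(free) == 0L)
    stop("at least one free parameter is required")
  free <- lapply(free, function(f) {
    if (is.null(f$name) || is.null(f$lower) || is.null(f$upper))
      stop("each free parameter needs name, lower, upper")
    if (!is.finite(f$lower) || !is.finite(f$upper) || f$lower >= f$upper)
      stop("free parameter '", f$name, "': bounds must be finite, lower < upper")
    param_get(circuit, f$name) # validates addressability
    if (is.null(f$log))
      f$log <- grepl("^(km|kx|gm|gx|K)", f$name)
    if (f$log && f$lower <= 0)
      stop("free parameter '", f$name, "': log-scale bounds must be positive")
    f
  })
  opts <- utils::modifyList(
    list(n_points = 64L, safety_factor = 4, dt = NULL, n_runs = 2000L),
    solver_opts)
  structure(list(circuit = circuit, free = free, dataset = dataset,
                 simulator = simulator, budget = as.integer(budget),
                 seed = as.integer(seed), solver_opts = opts),
            class = "calibration_problem")
}

# --- parameter addressing ---------------------------------------------------

parse_param_name <- function(name) {
  m <- regmatches(name, regexec("^(km|kx|gm|gx|eps)([0-9]+)$", name))[[1L]]
  if (length(m) == 3L)
    return(list(field = m[2L], i = as.integer(m[3L])))
  m <- regmatches(name, regexec("^(K|n)_([0-9]+)_([0-9]+)$", name))[[1L]]
  if (length(m) == 4L)
    return(list(field = if (m[2L] == "K") "K" else "n_hill",
                i = as.integer(m[3L]), j = as.integer(m[4L])))
  stop("unrecognized parameter name: '", name, "'")
}

param_get <- function(circuit, name) {
  a <- parse_param_name(name)
  if (a$i > circuit$n_genes || (!is.null(a$j) && a$j > circuit$n_genes))
    stop("parameter '", name, "': gene index out of range")
  if (is.null(a$j)) circuit[[a$field]][a$i]
  else {
    if (circuit$topology[a$i, a$j] == 0L)
      stop("parameter '", name, "': no edge at [", a$i, ",", a$j, "]")
    circuit[[a$field]][a$i, a$j]
  }
}

param_set <- function(circuit, name, value) {
  a <- parse_param_name(name)
  if (is.null(a$j)) circuit[[a$field]][a$i] <- value
  else circuit[[a$field]][a$i, a$j] <- value
  circuit
}

# free-parameter vector <-> search space (log slots exponentiated)
theta_bounds <- function(problem) {
  lower <- vapply(problem$free, function(f)
    if (f$log) log(f$lower) else f$lower, numeric(1L))
  upper <- vapply(problem$free, function(f)
    if (f$log) log(f$upper) else f$upper, numeric(1L))
  list(lower = lower, upper = upper)
}

theta_to_circuit <- function(problem, theta) {
  circuit <- problem$circuit
  for (k in seq_along(problem$free)) {
    f <- problem$free[[k]]
    value <- if (f$log) exp(theta[k]) else theta[k]
    circuit <- param_set(circuit, f$name, value)
  }
  validate_circuit(circuit)
}

# --- model distributions on the data bins -----------------------------------

model_histograms <- function(problem, circuit) {
  ds <- problem$dataset
  if (problem$simulator == "pide") {
    opts <- problem$solver_opts
    grid <- make_grid(circuit, n_points = opts$n_points,
                      safety_factor = opts$safety_factor)
    snaps <- pide_solve(circuit, ds$times, grid = grid, dt = opts$dt)
    lapply(snaps, function(f) {
      if (length(ds$genes) < f$grid$n_genes && length(ds$genes) == 1L)
        f <- field_marginal(f, ds$genes)
      masses <- bin_field(f, ds$edges)
      masses[masses < 0] <- 0
      masses / sum(masses)
    })
  } else {
    ens <- ssa_ensemble(circuit, ds$times, n_runs = problem$solver_opts$n_runs,
                        seed = problem$seed)
    lapply(seq_along(ds$times), function(k) {
      ensemble_histogram(ens, ds$edges, time_index = k, genes = ds$genes)$values
    })
  }
}

#' Calibration cost of a free-parameter vector
#'
#' Builds the circuit from `theta` (log-scale slots exponentiated),
#' simulates the chosen backend to all sampling times, aggregates the model
#' distributions onto the data bins and returns the summed KL divergence
#' `sum_t KL(data_t || model_t)`. Failed or non-finite simulations return a
#' large finite penalty (1e6 plus a term pulling back toward the bound-box
#' centre) instead of raising, keeping the optimization landscape finite.
#'
#' @param theta free-parameter vector in search (possibly log) space.
#' @param problem a `calibration_problem`.
#' @return Nonnegative scalar cost (or penalty value).
#' @export
calibration_cost <- function(theta, problem) {
  bounds <- theta_bounds(problem)
  theta <- clip_box(theta, bounds$lower, bounds$upper)
  penalty <- function() {
    mid <- (bounds$lower + bounds$upper) / 2
    1e6 + sum(abs(theta - mid) / (bounds$upper - bounds$lower))
  }
  model <- tryCatch({
    circuit <- theta_to_circuit(problem, theta)
    model_histograms(problem, circuit)
  }, error = function(e) NULL)
  if (is.null(model)) return(penalty())
  cost <- 0
  for (k in seq_along(problem$dataset$times)) {
    mk <- model[[k]]
    if (any(!is.finite(mk))) return(penalty())
    cost <- cost + kl_divergence(problem$dataset$values[[k]], mk)
  }
  if (!is.finite(cost)) return(penalty())
  cost
}

#' Fit a calibration problem
#'
#' Runs the scatter-search optimizer ([minlp_minimize()]) on
#' [calibration_cost()] and decodes the best parameter vector. Deterministic
#' given the problem seed.
#'
#' @param problem a `calibration_problem`.
#' @return A list of class `calibration_fit`: the underlying `optim_result`,
#'   the fitted `circuit`, and `estimates` (data frame of free-parameter
#'   names and fitted natural-scale values).
#' @export
calibrate_circuit <- function(problem) {
  bounds <- theta_bounds(problem)
  res <- minlp_minimize(function(th) calibration_cost(th, problem),
                        lower = bounds$lower, upper = bounds$upper,
                        budget = problem$budget, seed = problem$seed)
  circuit <- theta_to_circuit(problem, res$par)
  estimates <- data.frame(
    name = vapply(problem$free, `[[`, "", "name"),
    value = vapply(seq_along(problem$free), function(k) {
      f <- problem$free[[k]]
      if (f$log) exp(res$par[k]) else res$par[k]
    }, numeric(1L)))
  structure(list(result = res, circuit = circuit, estimates = estimates,
                 problem = problem),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> cost ", format(x$result$value), " after ",
      x$result$n_eval, " evaluations\n", sep = "")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

# --- dataset serialization --------------------------------------------------

#' Write a histogram dataset to delimited text
#'
#' Long format: `time, bin_low, bin_high, mass` for 1-D marginals;
#' `time, bin_i, bin_j, mass` (1-based bin indices) for 2-D joints, with the
#' bin edges carried in header comments.
#' @param dataset a `histogram_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nd <- length(dataset$edges)
  writeLines(c("# stochcirc histogram dataset",
               paste0("# genes: ", paste(dataset$genes, collapse = " ")),
               vapply(seq_len(nd), function(d)
                 paste0("# edges_", d, ": ",
                        paste(format(dataset$edges[[d]], digits = 15),
                              collapse = " ")), "")), con)
  rows <- do.call(rbind, lapply(seq_along(dataset$times), function(k) {
    v <- dataset$values[[k]]
    if (nd == 1L) {
      e <- dataset$edges[[1L]]
      data.frame(time = dataset$times[k], bin_low = e[-length(e)],
                 bin_high = e[-1L], mass = as.numeric(v))
    } else {
      ij <- expand.grid(bin_i = seq_len(dim(v)[1L]),
                        bin_j = seq_len(dim(v)[2L]))
      data.frame(time = dataset$times[k], ij, mass = as.numeric(v))
    }
  }))
  utils::write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a histogram dataset written by [write_dataset()]
#' @param path input path.
#' @return A `histogram_dataset`.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  genes <- as.integer(strsplit(sub("^# genes: *", "",
                                   grep("^# genes:", hdr, value = TRUE)),
                               " +")[[1L]])
  edges <- lapply(seq_along(genes), function(d) {
    ln <- grep(paste0("^# edges_", d, ":"), hdr, value = TRUE)
    as.numeric(strsplit(sub(paste0("^# edges_", d, ": *"), "", ln), " +")[[1L]])
  })
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  times <- sort(unique(df$time))
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  values <- lapply(times, function(tt) {
    sub <- df[df$time == tt, , drop = FALSE]
    v <- array(0, nb)
    if (length(genes) == 1L) {
      idx <- match(round(sub$bin_low, 9), round(edges[[1L]][-length(edges[[1L]])], 9))
      v[idx] <- sub$mass
    } else {
      v[cbind(sub$bin_i, sub$bin_j)] <- sub$mass
    }
    v
  })
  histogram_dataset(times, values, edges, genes = genes)
}
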