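test_that("FFT and direct autocorrelation estimators agree to roundoff", {
  set.seed(14)
  for (n in c(256L, 1000L)) {
    x <- cumsum(rnorm(n)) + rnorm(n)
    max_lag <- floor(n / 5)
    expect_equal(autocorr(x, max_lag, method = "fft"),
                 autocorr(x, max_lag, method = "direct"), tolerance = 1e-10)
  }
  expect_error(autocorr(rnorm(10), max_lag = 10), "max_lag")
  expect_error(autocorr(rep(1, 50), max_lag = 5), "constant")
})

test_that("the second peak of a sinusoid sits at its period with height near 1", {
  x <- sin(2 * pi * (1:8000) / 20)
  pk <- autocorr_second_peak(x, burn_in = 0, max_lag = 100)
  expect_equal(pk$lag, 20L)
  expect_equal(pk$height, 1, tolerance = 0.02)
  expect_false(pk$degenerate)
})

test_that("white noise has no meaningful second peak", {
  set.seed(3)
  n <- 20000
  x <- rnorm(n)
  pk <- autocorr_second_peak(x, burn_in = 0, max_lag = 500)
  expect_lt(pk$height, 3 / sqrt(n))
})

test_that("constant series are flagged as degenerate", {
  pk <- autocorr_second_peak(rep(4, 5000), burn_in = 100, max_lag = 1000)
  expect_equal(pk$height, 0)
  expect_true(pk$degenerate)
  expect_true(is.na(pk$lag))
})

test_that("decision vectors decode to valid circuits and round-trip", {
  base <- gene_circuit(matrix(0L, 2, 2), km = 4, kx = 50, gm = 10, gx = 1)
  prob <- design_problem(base, objective = function(circ) 0,
                         topology_free = rbind(c(1, 2), c(2, 1)),
                         coop_free = rbind(c(1, 2)),
                         real_free = list(list(name = "km1", lower = 1,
                                               upper = 20)),
                         edge_defaults = list(K = 6, n = 3))
  # repression edge switched on picks up the default (K, n); free
  # cooperativity overrides it; free real slot decoded from log scale
  circ <- decode_design(prob, c(-1, 0, 4, log(7)))
  expect_equal(circ$topology[1, 2], -1L)
  expect_equal(circ$topology[2, 1], 0L)
  expect_equal(circ$K[1, 2], 6)
  expect_equal(circ$n_hill[1, 2], 4)
  expect_equal(circ$km[1], 7)
  # switched-off slot drops its regulation parameters
  expect_true(is.na(circ$K[2, 1]) && is.na(circ$n_hill[2, 1]))
  # round-trip on the free slots
  z <- encode_design(prob, circ)
  expect_equal(decode_design(prob, z)$topology, circ$topology)
  expect_equal(decode_design(prob, z)$km, circ$km)
  expect_error(decode_design(prob, c(-2, 0, 4, log(7))), "bounds")
})

test_that("an all-fixed design problem returns the base circuit unchanged", {
  base <- fixture_circuit("toggle_switch")
  prob <- design_problem(base, objective = function(circ) 42)
  res <- design_circuit(prob)
  expect_equal(res$circuit$topology, base$topology)
  expect_equal(res$value, 42)
})

test_that("the stationary-target objective discriminates matching circuits", {
  circ <- fixture_circuit("constitutive")
  sopts <- list(n_points = 64, tol = 5e-4)
  st <- pide_stationary(circ, grid = make_grid(circ, n_points = 64),
                        tol = 5e-4)
  edges <- seq(0, 160, by = 8)
  target <- normalize_hist(bin_field(st, list(edges)))
  # a circuit's own stationary law scores (near) zero
  expect_lt(objective_target_stationary(circ, target, list(edges),
                                        solver_opts = sopts), 1e-3)
  # a circuit with double the mean scores clearly worse
  off <- circ; off$km <- circ$km * 2
  expect_gt(objective_target_stationary(off, target, list(edges),
                                        solver_opts = sopts), 0.1)
  # an unregulated gene cannot match a bimodal target
  bimix <- 0.5 * dnorm((edges[-1] + edges[-21]) / 2, 20, 6) +
           0.5 * dnorm((edges[-1] + edges[-21]) / 2, 120, 6)
  expect_gt(objective_target_stationary(circ, bimix / sum(bimix),
                                        list(edges), solver_opts = sopts),
            0.2)
})

test_that("the bimodality objective scores the toggle near zero by symmetry", {
  domains <- list(list(lower = c(12, 0), upper = c(80, 8)),
                  list(lower = c(0, 12), upper = c(8, 80)))
  sopts <- list(n_points = 41, tol = 5e-4)
  tog <- fixture_circuit("toggle_switch")
  st <- pide_stationary(tog, grid = make_grid(tog, n_points = 41), tol = 5e-4)
  m1 <- stochcirc:::domain_mass(st, domains[[1]])
  m2 <- stochcirc:::domain_mass(st, domains[[2]])
  expect_equal(m1, m2, tolerance = 0.02) # symmetric switch: equal masses
  cost_sym <- objective_bimodality(tog, domains,
                                   target_masses = c(m1, m2),
                                   min_mode_distance = 15,
                                   solver_opts = sopts)
  expect_lt(cost_sym, 0.02)

  # unimodal circuit: full hinge penalty at any positive mode distance
  cons2 <- gene_circuit(matrix(0L, 2, 2), km = 4, kx = 50, gm = 10, gx = 1)
  cost_uni <- objective_bimodality(cons2, domains,
                                   target_masses = c(0, 0),
                                   min_mode_distance = 10,
                                   solver_opts = sopts)
  expect_gte(cost_uni, 10 - 1e-9)

  # vacuous objective: empty domains, no mode-distance requirement
  far <- list(list(lower = c(74, 74), upper = c(77, 77)),
              list(lower = c(78, 78), upper = c(80, 80)))
  expect_equal(objective_bimodality(cons2, far, target_masses = c(0, 0),
                                    min_mode_distance = 0,
                                    solver_opts = sopts), 0,
               tolerance = 1e-6)
})

test_that("the oscillation objective separates oscillators from flat noise", {
  rep3 <- fixture_circuit("repressilator")
  cost_osc <- objective_oscillation(rep3, gene = 1, n_samples = 20000,
                                    burn_in = 2000, seed = 5)
  expect_lt(cost_osc, -0.1)
  cons <- fixture_circuit("constitutive")
  cost_flat <- objective_oscillation(cons, gene = 1, n_samples = 20000,
                                     burn_in = 2000, seed = 5)
  expect_lt(abs(cost_flat), 0.05)
  # determinism: the objective is a pure function of (circuit, seed)
  expect_identical(cost_osc,
                   objective_oscillation(rep3, gene = 1, n_samples = 20000,
                                         burn_in = 2000, seed = 5))
})

test_that("the dynamics-target objective is near zero for the generating circuit", {
  circ <- fixture_circuit("constitutive")
  edges <- seq(0, 160, by = 8)
  grid <- make_grid(circ, n_points = 64)
  snaps <- pide_solve(circ, c(2, 6), grid = grid)
  vals <- lapply(snaps, function(f) normalize_hist(bin_field(f, list(edges))))
  ds <- histogram_dataset(c(2, 6), vals, edges)
  expect_lt(objective_target_dynamics(circ, ds,
                                      solver_opts = list(n_points = 64)),
            1e-6)
  off <- circ; off$km <- 10
  expect_gt(objective_target_dynamics(off, ds,
                                      solver_opts = list(n_points = 64)),
            0.05)
})

test_that("design search respects its budget and keeps a monotone trace", {
  base <- gene_circuit(matrix(0L, 2, 2), km = 4, kx = 50, gm = 10, gx = 1)
  sopts <- list(n_points = 24, tol = 2e-3, max_iter = 20000)
  domains <- list(list(lower = c(12, 0), upper = c(80, 8)),
                  list(lower = c(0, 12), upper = c(8, 80)))
  objective <- function(circ)
    objective_bimodality(circ, domains, target_masses = c(0.45, 0.45),
                         min_mode_distance = 15, solver_opts = sopts)
  prob <- design_problem(base, objective,
                         topology_free = rbind(c(1, 2), c(2, 1)),
                         edge_defaults = list(K = 6, n = 3),
                         budget = 30, seed = 2)
  res <- design_circuit(prob)
  expect_lte(res$result$n_eval, 30L)
  expect_true(all(diff(res$result$trace) <= 0))
  expect_s3_class(res$circuit, "gene_circuit")
})
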