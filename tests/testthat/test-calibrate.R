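test_that("KL divergence matches hand-computed reference values", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  # asymmetric: only the stated order is used in costs
  p <- c(0.8, 0.2); q <- c(0.4, 0.6)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_gte(kl_divergence(p, q), 0)
  expect_error(kl_divergence(c(1, 0), c(0.3, 0.3, 0.4)), "mismatched")
  # flooring keeps empty model bins finite
  expect_true(is.finite(kl_divergence(c(0.5, 0.5), c(1, 0))))
})

test_that("histogram datasets validate their structure", {
  edges <- seq(0, 10, by = 2)
  good <- histogram_dataset(1, list(rep(0.2, 5)), edges)
  expect_s3_class(good, "histogram_dataset")
  expect_error(histogram_dataset(1, list(rep(0.3, 5)), edges), "sum to 1")
  expect_error(histogram_dataset(c(1, 2), list(rep(0.2, 5)), edges),
               "one histogram per")
  path <- withr::local_tempfile(fileext = ".tsv")
  ds2 <- histogram_dataset(c(1, 3), list(c(0.5, 0.3, 0.2, 0, 0),
                                         c(0.1, 0.2, 0.3, 0.2, 0.2)), edges)
  write_dataset(ds2, path)
  back <- read_dataset(path)
  expect_equal(back$times, ds2$times)
  expect_equal(back$values, ds2$values, tolerance = 1e-12)
  expect_equal(back$edges, ds2$edges)
})

test_that("2-D joint datasets round-trip through the long text format", {
  circ <- fixture_circuit("toggle_switch")
  edges <- seq(0, 80, by = 10)
  pd <- make_pseudo_data(circ, t_points = c(2, 5), n_samples = 400,
                         edges = edges, seed = 8, genes = c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(pd$dataset, path)
  back <- read_dataset(path)
  expect_equal(back$values, pd$dataset$values, tolerance = 1e-12)
  expect_equal(back$genes, c(1L, 2L))
})

test_that("the cost vanishes at the generating parameters and rises around them", {
  circ <- fixture_circuit("constitutive")
  edges <- seq(0, 160, by = 8)
  grid <- make_grid(circ, n_points = 101)
  snaps <- pide_solve(circ, c(3, 8), grid = grid)
  vals <- lapply(snaps, function(f) normalize_hist(bin_field(f, list(edges))))
  ds <- histogram_dataset(c(3, 8), vals, edges)
  prob <- calibration_problem(
    circ, free = list(list(name = "km1", lower = 0.5, upper = 40)),
    dataset = ds, solver_opts = list(n_points = 101))
  theta_star <- log(4)
  cost_star <- calibration_cost(theta_star, prob)
  expect_lt(cost_star, 1e-6)
  # self-consistency: the truth beats random perturbations
  set.seed(11)
  for (draw in 1:20) {
    theta <- theta_star + runif(1, -1.5, 1.5)
    theta <- min(max(theta, log(0.5)), log(40))
    expect_gte(calibration_cost(theta, prob), cost_star)
  }
})

test_that("infeasible parameter regions yield the finite penalty, not errors", {
  circ <- fixture_circuit("constitutive")
  edges <- seq(0, 160, by = 16)
  ds <- histogram_dataset(5, list(rep(0.1, 10)), edges)
  # a free leakage allowed to go negative produces an invalid circuit
  prob <- calibration_problem(
    circ, free = list(list(name = "eps1", lower = -0.5, upper = 0.9)),
    dataset = ds, solver_opts = list(n_points = 64))
  val <- calibration_cost(-0.2, prob)
  expect_true(is.finite(val))
  expect_gte(val, 1e6)
})

test_that("problem construction validates its inputs", {
  circ <- fixture_circuit("constitutive")
  edges <- seq(0, 160, by = 16)
  ds <- histogram_dataset(5, list(rep(0.1, 10)), edges)
  expect_error(calibration_problem(circ, free = list(), dataset = ds),
               "free parameter")
  expect_error(calibration_problem(
    circ, free = list(list(name = "km9", lower = 1, upper = 2)),
    dataset = ds), "out of range")
  expect_error(calibration_problem(
    circ, free = list(list(name = "km1", lower = 2, upper = 1)),
    dataset = ds), "bounds")
  expect_error(calibration_problem(
    circ, free = list(list(name = "K_1_1", lower = 1, upper = 2)),
    dataset = ds), "no edge")
})

test_that("a single free transcription rate is recovered within 10%", {
  circ <- fixture_circuit("constitutive")
  edges <- seq(0, 160, by = 8)
  grid <- make_grid(circ, n_points = 101)
  snaps <- pide_solve(circ, c(2, 5, 10), grid = grid)
  vals <- lapply(snaps, function(f) normalize_hist(bin_field(f, list(edges))))
  ds <- histogram_dataset(c(2, 5, 10), vals, edges)
  prob <- calibration_problem(
    circ, free = list(list(name = "km1", lower = 0.5, upper = 40)),
    dataset = ds, budget = 60, seed = 2, solver_opts = list(n_points = 101))
  fit <- calibrate_circuit(prob)
  expect_lt(abs(fit$estimates$value - 4) / 4, 0.10)
  # best-so-far trace is nonincreasing
  expect_true(all(diff(fit$result$trace) <= 0))
})

test_that("a stationary snapshot identifies km/gx even when both drift", {
  # the 1-D stationary law is Gamma(km/gx, kx/gm): only the ratio km/gx is
  # identifiable from a single late snapshot
  circ <- fixture_circuit("constitutive")
  edges <- seq(0, 160, by = 8)
  grid <- make_grid(circ, n_points = 64)
  snap <- pide_solve(circ, 25, grid = grid)[[1]]
  ds <- histogram_dataset(25, list(normalize_hist(bin_field(snap, list(edges)))),
                          edges)
  prob <- calibration_problem(
    circ, free = list(list(name = "km1", lower = 0.5, upper = 40),
                      list(name = "gx1", lower = 0.1, upper = 10)),
    dataset = ds, budget = 120, seed = 6, solver_opts = list(n_points = 64))
  fit <- calibrate_circuit(prob)
  a_hat <- fit$estimates$value[1] / fit$estimates$value[2]
  expect_lt(abs(a_hat - 4) / 4, 0.10)
})

test_that("a sampling-only budget still returns the best initial draw", {
  circ <- fixture_circuit("constitutive")
  edges <- seq(0, 160, by = 16)
  grid <- make_grid(circ, n_points = 64)
  snap <- pide_solve(circ, 5, grid = grid)[[1]]
  ds <- histogram_dataset(5, list(normalize_hist(bin_field(snap, list(edges)))),
                          edges)
  prob <- calibration_problem(
    circ, free = list(list(name = "km1", lower = 0.5, upper = 40)),
    dataset = ds, budget = 10, seed = 3, solver_opts = list(n_points = 64))
  fit <- calibrate_circuit(prob)
  expect_true(is.finite(fit$result$value))
  expect_lte(fit$result$n_eval, 10L)
})
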