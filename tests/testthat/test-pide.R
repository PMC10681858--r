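test_that("grid construction follows the stationary-mean truncation rule", {
  circ <- plain_gene(km = 10, kx = 5, gm = 5, gx = 1)
  g <- make_grid(circ, n_points = 50, safety_factor = 4)
  expect_equal(g$x_max, 40) # 4 * km kx / (gm gx)
  expect_equal(g$nodes[[1]][1], 0)
  expect_true(all(diff(g$nodes[[1]]) > 0))
  expect_error(make_grid(circ, n_points = 50, safety_factor = 0),
               "safety_factor")
  expect_error(make_grid(circ, n_points = 8), "n_points")

  # two identical genes get identical per-dimension grids
  twin <- gene_circuit(matrix(0L, 2, 2), km = 10, kx = 5, gm = 5, gx = 1)
  g2 <- make_grid(twin, n_points = 32)
  expect_identical(g2$nodes[[1]], g2$nodes[[2]])

  four <- gene_circuit(matrix(0L, 4, 4), km = 1, kx = 1, gm = 1, gx = 1)
  expect_error(make_grid(four, n_points = 16), "3 genes")
})

test_that("burst quadrature reproduces the exponential kernel's mass profile", {
  # row k of the kernel matrix integrates beta over [0, x_k]:
  # the exact value is 1 - exp(-x_k/b)
  circ <- fixture_circuit("constitutive")
  g <- make_grid(circ, n_points = 200)
  b <- burst_sizes(circ)
  B <- stochcirc:::burst_matrix(g$nodes[[1]], b)
  got <- rowSums(B)
  expected <- 1 - exp(-g$nodes[[1]] / b)
  # product integration makes the row mass exact up to roundoff
  expect_equal(got, expected, tolerance = 1e-12)
  expect_true(all(B >= 0))
})

test_that("pure degradation contracts the mean by exp(-gx dt) per step", {
  # with a negligible transcription rate the dynamics reduce to the
  # advection term, solved exactly along characteristics
  circ <- gene_circuit(matrix(0L), km = 1e-9, kx = 100, gm = 10, gx = 1)
  g <- structure(list(n_genes = 1L, n_points = 128L, x_max = 160,
                      h = 160 / 127, nodes = list(seq(0, 160, length.out = 128))),
                 class = "pide_grid")
  P0 <- distribution_field(g, gamma_on_grid(g$nodes[[1]], 4, 10))
  dt <- 0.02
  f <- P0
  for (s in 1:25) f <- pide_step(f, circ, dt)
  mean0 <- trapz(g$nodes[[1]] * P0$P, g$nodes[[1]])
  mean1 <- trapz(g$nodes[[1]] * f$P, g$nodes[[1]])
  expect_equal(mean1 / mean0, exp(-1 * 25 * dt), tolerance = 0.01)
  expect_equal(field_mass(f), 1, tolerance = 1e-12)
})

test_that("each step conserves mass and positivity on every fixture", {
  cases <- list(
    list(circ = fixture_circuit("constitutive"), n = 200L),
    list(circ = fixture_circuit("toggle_switch"), n = 61L),
    list(circ = fixture_circuit("repressilator"), n = 64L))
  for (case in cases) {
    grid <- make_grid(case$circ, n_points = case$n)
    f <- default_p0(case$circ, grid)
    dt <- pide_default_dt(case$circ, grid)
    ops <- pide_operators(case$circ, grid, dt)
    for (s in 1:5) {
      f <- pide_step(f, case$circ, dt, ops)
      expect_lt(abs(attr(f, "mass_pre") - 1), 1e-3)
      expect_lt(attr(f, "clipped"), 1e-6)
      expect_equal(field_mass(f), 1, tolerance = 1e-12)
      expect_true(all(f$P >= 0))
    }
    # without renormalization the drift still stays within the same bound
    fr <- pide_step(f, case$circ, dt, ops, renormalize = FALSE)
    expect_lt(abs(field_mass(fr) - 1), 1e-3)
  }
})

test_that("oversized steps substep automatically with a warning", {
  circ <- fixture_circuit("constitutive")
  grid <- make_grid(circ, n_points = 64)
  f <- default_p0(circ, grid)
  expect_warning(pide_step(f, circ, dt = 1), "substepping")
  expect_error(pide_step(f, circ, dt = 0), "dt")
})

test_that("solving to t = 0 returns the initial field unchanged", {
  circ <- fixture_circuit("constitutive")
  grid <- make_grid(circ, n_points = 64)
  P0 <- default_p0(circ, grid)
  out <- pide_solve(circ, t_points = 0, P0 = P0)
  expect_equal(out[[1]]$P, P0$P)
})

test_that("snapshots converge in L1 toward the stationary solution", {
  circ <- fixture_circuit("constitutive")
  grid <- make_grid(circ, n_points = 101)
  P0 <- distribution_field(grid, rep(1, 101)) # far-from-stationary start
  snaps <- pide_solve(circ, t_points = c(1, 2, 4, 8, 16), P0 = P0)
  target <- distribution_field(grid, gamma_on_grid(grid$nodes[[1]], 4, 10),
                               normalize = FALSE)
  dists <- vapply(snaps, field_l1, numeric(1), f2 = target)
  expect_true(all(diff(dists) < 0))
  expect_lt(dists[length(dists)], 0.05)
})

test_that("halving the time step changes the solution consistently", {
  circ <- fixture_circuit("constitutive")
  grid <- make_grid(circ, n_points = 101)
  dt <- pide_default_dt(circ, grid)
  s1 <- pide_solve(circ, t_points = 5, grid = grid, dt = dt)[[1]]
  s2 <- pide_solve(circ, t_points = 5, grid = grid, dt = dt / 2)[[1]]
  s4 <- pide_solve(circ, t_points = 5, grid = grid, dt = dt / 4)[[1]]
  d12 <- field_l1(s1, s2)
  d24 <- field_l1(s2, s4)
  expect_lt(d12, 0.05)
  expect_lt(d24, d12) # first-order-in-time consistency
})

test_that("the discretized operator accepts the Gamma law as stationary", {
  # residual check of the closed form used as oracle: one step started AT
  # the Gamma density must barely move it
  circ <- fixture_circuit("constitutive")
  grid <- make_grid(circ, n_points = 200)
  gam <- distribution_field(grid, gamma_on_grid(grid$nodes[[1]], 4, 10))
  dt <- pide_default_dt(circ, grid)
  stepped <- pide_step(gam, circ, dt)
  expect_lt(field_l1(stepped, gam) / dt, 0.05)
})

test_that("stationary solution matches the Gamma law of bursty expression", {
  circ <- fixture_circuit("constitutive")
  grid <- make_grid(circ, n_points = 200)
  P0 <- distribution_field(grid, rep(1, 200))
  st <- pide_stationary(circ, P0 = P0, tol = 1e-5)
  gam <- gamma_on_grid(grid$nodes[[1]], shape = circ$km / circ$gx,
                       scale = circ$kx / circ$gm)
  expect_lt(trapz(abs(st$P - gam), grid$nodes[[1]]), 0.02)
  mean_st <- trapz(grid$nodes[[1]] * st$P, grid$nodes[[1]])
  expect_equal(mean_st, 40, tolerance = 0.02)
  expect_error(pide_stationary(circ, grid = grid, tol = -1), "tol")
  expect_error(pide_stationary(circ, grid = grid, tol = 1e-9, max_iter = 50,
                               check_every = 25), "did not converge")
})

test_that("refining the grid reduces the error against the Gamma oracle", {
  circ <- fixture_circuit("constitutive")
  errs <- vapply(c(50L, 100L, 200L), function(n) {
    grid <- make_grid(circ, n_points = n)
    st <- pide_stationary(circ, grid = grid, tol = 1e-5)
    gam <- gamma_on_grid(grid$nodes[[1]], 4, 10)
    trapz(abs(st$P - gam), grid$nodes[[1]])
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("toggle switch stationary field is bimodal with symmetric modes", {
  circ <- fixture_circuit("toggle_switch")
  st <- pide_stationary(circ, grid = make_grid(circ, n_points = 61),
                        tol = 1e-4)
  modes <- find_modes(st, min_value = 1e-9)
  expect_gte(nrow(modes), 2L)
  top2 <- modes[1:2, ]
  # anticorrelated high/low states, mirror images of each other
  expect_equal(sort(c(top2$x1[1], top2$x2[1])), sort(c(top2$x1[2], top2$x2[2])))
  expect_gt(abs(top2$x1[1] - top2$x2[1]), 10)
})

test_that("marginals and bin aggregation preserve probability mass", {
  circ <- fixture_circuit("toggle_switch")
  grid <- make_grid(circ, n_points = 41)
  f <- pide_solve(circ, t_points = 3, grid = grid)[[1]]
  m1 <- field_marginal(f, 1)
  expect_equal(trapz(m1$P, m1$grid$nodes[[1]]), 1, tolerance = 1e-9)
  edges <- seq(0, 80, by = 8)
  h1 <- bin_field(m1, list(edges))
  expect_equal(sum(h1), 1, tolerance = 1e-9)
  h2 <- bin_field(f, list(edges, edges))
  expect_equal(sum(h2), 1, tolerance = 1e-9)
  expect_equal(as.numeric(rowSums(h2)), as.numeric(h1), tolerance = 1e-9)
})

test_that("distribution fields round-trip through the text format", {
  circ <- fixture_circuit("constitutive")
  grid <- make_grid(circ, n_points = 64)
  f <- default_p0(circ, grid)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field(f, path)
  back <- read_field(path)
  expect_equal(back$P, f$P, tolerance = 1e-12)
  expect_equal(back$t, f$t)
  expect_equal(back$grid$x_max, f$grid$x_max)
})
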