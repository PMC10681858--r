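#' Tensor grid for the protein-level distribution
#'
#' Builds a uniform per-dimension grid on `[0, x_max_i]` with
#' `x_max_i = safety_factor * km_i * kx_i / (gm_i * gx_i)`, the deterministic
#' stationary mean at full promoter activity. The default safety factor of 4
#' leaves ample room for the upper distribution tail; the solver assumes the
#' density is negligible beyond `x_max`.
#'
#' @param circuit a `gene_circuit` (at most 3 genes on dense tensor grids).
#' @param n_points points per dimension (scalar or per-gene vector, >= 16).
#' @param safety_factor multiple of the full-activity stationary mean (> 0).
#' @return An object of class `pide_grid`: `n_genes`, `n_points`, `x_max`,
#'   `h`, and `nodes` (list of per-dimension coordinate vectors starting at 0).
#' @export
make_grid <- function(circuit, n_points = 128L, safety_factor = 4) {
  validate_circuit(circuit)
  n <- circuit$n_genes
  if (n > 3L)
    stop("dense tensor grids are limited to 3 genes; got ", n)
  if (!is.numeric(safety_factor) || safety_factor <= 0)
    stop("safety_factor must be > 0")
  n_points <- rep(as.integer(n_points), length.out = n)
  if (any(n_points < 16L)) stop("n_points must be >= 16 per dimension")
  x_max <- safety_factor * circuit$km * circuit$kx / (circuit$gm * circuit$gx)
  nodes <- lapply(seq_len(n), function(i)
    seq(0, x_max[i], length.out = n_points[i]))
  structure(list(n_genes = n, n_points = n_points, x_max = x_max,
                 h = x_max / (n_points - 1L), nodes = nodes),
            class = "pide_grid")
}

#' Probability distribution field on a grid
#'
#' Wraps nonnegative density values on a tensor grid, normalized to unit
#' trapezoidal mass.
#'
#' @param grid a `pide_grid`.
#' @param values nonnegative array of dimension `grid$n_points`.
#' @param t time stamp of the field.
#' @param normalize renormalize to unit mass (default `TRUE`).
#' @return An object of class `distribution_field` with elements `grid`,
#'   `P` (density array) and `t`.
#' @export
distribution_field <- function(grid, values, t = 0, normalize = TRUE) {
  P <- array(values, grid$n_points)
  if (any(P < 0)) stop("density values must be nonnegative")
  if (normalize) {
    m <- sum(P * weight_array(grid$nodes))
    if (m <= 0) stop("cannot normalize a zero field")
    P <- P / m
  }
  structure(list(grid = grid, P = P, t = t), class = "distribution_field")
}

#' @export
print.distribution_field <- function(x, ...) {
  cat("<distribution_field> dims ", paste(x$grid$n_points, collapse = " x "),
      ", t = ", format(x$t), ", mass = ", format(field_mass(x)), "\n", sep = "")
  invisible(x)
}

#' Total trapezoidal mass of a field
#' @param field a `distribution_field`.
#' @return Scalar mass (1 after normalization).
#' @export
field_mass <- function(field) sum(field$P * weight_array(field$grid$nodes))

#' L1 distance between two fields on the same grid
#' @param f1,f2 `distribution_field`s sharing a grid.
#' @return Nonnegative scalar \eqn{\int |P_1 - P_2|}.
#' @export
field_l1 <- function(f1, f2) {
  if (!identical(dim(f1$P), dim(f2$P))) stop("fields live on different grids")
  sum(abs(f1$P - f2$P) * weight_array(f1$grid$nodes))
}

#' Default initial distribution
#'
#' Product of independent Gamma densities with per-gene shape
#' `a_i = km_i/gx_i` and scale `b_i = kx_i/gm_i` (the stationary law of each
#' gene at full promoter activity), discretized on the grid and normalized.
#'
#' @param circuit a `gene_circuit`.
#' @param grid a `pide_grid`.
#' @return A `distribution_field` at `t = 0`.
#' @export
default_p0 <- function(circuit, grid) {
  a <- circuit$km / circuit$gx
  b <- circuit$kx / circuit$gm
  margs <- lapply(seq_len(grid$n_genes), function(i) {
    v <- stats::dgamma(grid$nodes[[i]], shape = a[i], scale = b[i])
    v[!is.finite(v)] <- max(v[is.finite(v)], 1) # shape < 1: cap the 0-node pole
    v
  })
  P <- margs[[1L]]
  if (grid$n_genes > 1L)
    for (k in 2L:grid$n_genes) P <- outer(P, margs[[k]])
  distribution_field(grid, P, t = 0)
}

# --- solver internals -------------------------------------------------------

# Exact advection along characteristics of d/dt P = d/dx (g x P) over dt:
# P_new(x) = e^{g dt} P_old(x e^{g dt}), linear interpolation at the foot,
# zero beyond x_max. Returned as a dense matrix acting on grid lines.
advection_matrix <- function(nodes, g, dt) {
  n <- length(nodes)
  h <- nodes[2L] - nodes[1L]
  fac <- exp(g * dt)
  foot <- nodes * fac
  M <- matrix(0, n, n)
  pos <- foot / h
  k0 <- pmin(floor(pos), n - 1L)   # inside-domain feet only
  w <- pos - k0
  inside <- foot <= nodes[n] + 1e-12
  for (k in which(inside)) {
    j <- k0[k] + 1L
    if (j < n) {
      M[k, j] <- M[k, j] + fac * (1 - w[k])
      M[k, j + 1L] <- M[k, j + 1L] + fac * w[k]
    } else {
      M[k, n] <- M[k, n] + fac * (1 - (pos[k] - (n - 1L)))
    }
  }
  # Mass fixer: under pure decay the flow points toward 0, so no probability
  # leaves [0, x_max] and each basis function must keep exactly its own
  # integral. Rescaling columns to their quadrature weight makes the
  # advection half-step exactly conservative without harming positivity
  # (the correction factors are 1 + O(h^2)).
  wq <- trapz_weights(nodes)
  colmass <- as.numeric(wq %*% M)
  scale <- ifelse(colmass > 0, wq / colmass, 1)
  M * rep(scale, each = n)
}

# Product-integration matrix for the burst gain integral along one
# dimension: row k gives \int_0^{x_k} beta(x_k - y) f(y) dy exactly for the
# piecewise-linear interpolant of f, with beta the exponential kernel of
# mean b. With q = exp(-h/b) and r = b/h the weights have the closed form
#   B[k,l] = r (1-q)^2 q^(k-l-1)      for 0 < l < k,
#   B[k,0] = q^(k-1) (r (1-q) - q),   B[k,k] = 1 - r (1-q),
# (0-based indices), so each row sums to exactly 1 - q^k, the true kernel
# mass over [0, x_k]. This keeps the pre-normalization mass drift at the
# level of the kernel's tail beyond the grid rather than of a quadrature
# error.
burst_matrix <- function(nodes, b) {
  n <- length(nodes)
  h <- nodes[2L] - nodes[1L]
  q <- exp(-h / b)
  r <- b / h
  kk <- 0:(n - 1L)
  pw <- outer(kk, kk, `-`) - 1L # k - l - 1
  B <- matrix(0, n, n)
  interior <- pw >= 0L & col(B) >= 2L
  B[interior] <- r * (1 - q)^2 * q^pw[interior]
  B[, 1L] <- q^(kk - 1L) * (r * (1 - q) - q)
  diag(B) <- 1 - r * (1 - q)
  B[1L, ] <- 0 # integral over [0, 0]
  B
}

#' Precompute the semi-Lagrangian operators for a circuit and grid
#'
#' Builds, once per `(circuit, grid, dt)`: the per-dimension exact advection
#' matrices, the burst-kernel quadrature matrices (exponential kernel with
#' mean `b_i = kx_i/gm_i`), the promoter-activity arrays `c_i` on the full
#' grid, and the quadrature weight array. [pide_step()] accepts the result
#' through its `ops` argument to avoid rebuilding inside time loops.
#'
#' @param circuit a `gene_circuit`.
#' @param grid a `pide_grid`.
#' @param dt time step the advection matrices are built for.
#' @return A list of operators (class `pide_ops`).
#' @export
pide_operators <- function(circuit, grid, dt) {
  n <- grid$n_genes
  b <- burst_sizes(circuit)
  list(
    dt = dt,
    adv = lapply(seq_len(n), function(i)
      advection_matrix(grid$nodes[[i]], circuit$gx[i], dt)),
    burst = lapply(seq_len(n), function(i)
      burst_matrix(grid$nodes[[i]], b[i])),
    input = lapply(seq_len(n), function(i)
      array(evaluate_input_gene(circuit, i, grid$nodes), grid$n_points)),
    W = weight_array(grid$nodes),
    km = circuit$km
  )
}

# Largest step honouring the scheme's stability constraint. The advection
# half-step is unconditionally stable (backward characteristic tracing), so
# the binding limit is positivity/accuracy of the explicit Euler jump
# update: dt * km * c must stay well below 1.
pide_dt_stable <- function(circuit, grid) {
  0.25 / max(circuit$km)
}

#' Default PIDE time step
#'
#' A two-advection-cell step, `2 / max_i(gx_i * (n_points_i - 1))`, capped
#' by the jump-term stability bound. The choice balances the scheme's two
#' error sources: each step re-interpolates at the characteristic feet, so
#' accumulated interpolation diffusion grows as `dt` shrinks, while the
#' explicit Euler jump error grows linearly in `dt`; on the analytically
#' solvable constitutive circuit the balance sits near a foot displacement
#' of two cells at the domain edge.
#' @param circuit a `gene_circuit`.
#' @param grid a `pide_grid`.
#' @return Scalar time step.
#' @export
pide_default_dt <- function(circuit, grid) {
  min(2 / max(circuit$gx * (grid$n_points - 1L)),
      pide_dt_stable(circuit, grid))
}

#' One semi-Lagrangian step of the PIDE
#'
#' Advances the distribution by `dt` using first-order dimensional splitting.
#' For each dimension `i` in index order: (a) the degradation drift
#' \eqn{\partial_t P = \partial_{x_i}(\gamma_{x_i} x_i P)} is solved exactly
#' along characteristics with linear interpolation at the characteristic foot
#' and zero extension beyond `x_max`; (b) the burst jump term
#' \eqn{k_{m_i}[\int_0^{x_i}\beta_i(x_i-y)c_i(y)P\,dy - c_i(x)P]}
#' (exponential burst kernel, gain and loss) is applied by explicit Euler
#' with product-integration quadrature along dimension `i` (exact for the
#' piecewise-linear interpolant). Tiny negative values are clipped to zero and
#' the field is renormalized to unit mass unless `renormalize = FALSE`.
#'
#' If `dt` exceeds the stability bound the step is subdivided automatically
#' (with a warning).
#'
#' @param field a `distribution_field`.
#' @param circuit a `gene_circuit`.
#' @param dt time step (> 0).
#' @param ops optional precomputed [pide_operators()] for this `dt`.
#' @param renormalize renormalize mass after the step (default `TRUE`).
#' @return The advanced `distribution_field`; attributes `mass_pre` (total
#'   mass before clipping/renormalization) and `clipped` (negative mass
#'   removed) expose the conservation diagnostics.
#' @export
pide_step <- function(field, circuit, dt, ops = NULL, renormalize = TRUE) {
  if (dt <= 0) stop("dt must be > 0")
  dt_max <- pide_dt_stable(circuit, field$grid)
  if (dt > dt_max * (1 + 1e-9)) {
    nsub <- ceiling(dt / dt_max)
    warning(sprintf("dt = %g exceeds stability bound %g; substepping x%d",
                    dt, dt_max, nsub))
    sub <- dt / nsub
    ops <- pide_operators(circuit, field$grid, sub)
    for (s in seq_len(nsub))
      field <- pide_step(field, circuit, sub, ops, renormalize)
    return(field)
  }
  if (is.null(ops) || abs(ops$dt - dt) > 1e-12 * max(dt, 1))
    ops <- pide_operators(circuit, field$grid, dt)
  P <- field$P
  for (i in seq_len(field$grid$n_genes)) {
    P <- apply_dim(P, i, function(Pm) ops$adv[[i]] %*% Pm)
    CP <- ops$input[[i]] * P
    gain <- apply_dim(CP, i, function(Pm) ops$burst[[i]] %*% Pm)
    P <- P + dt * ops$km[i] * (gain - CP)
  }
  mass_pre <- sum(P * ops$W)
  clipped <- -sum(pmin(P, 0) * ops$W)
  P[P < 0] <- 0
  if (renormalize) P <- P / sum(P * ops$W)
  out <- structure(list(grid = field$grid, P = P, t = field$t + dt),
                   class = "distribution_field")
  attr(out, "mass_pre") <- mass_pre
  attr(out, "clipped") <- clipped
  out
}

#' Solve the PIDE forward in time
#'
#' Repeatedly applies [pide_step()] with snapshots at `t_points`, subdividing
#' the step so snapshot times are hit exactly. Fully deterministic.
#'
#' @param circuit a `gene_circuit`.
#' @param t_points increasing snapshot times (first may equal `P0$t`).
#' @param P0 initial `distribution_field` (default [default_p0()]).
#' @param grid grid used when `P0` is `NULL` (default [make_grid()]).
#' @param dt internal time step (default [pide_default_dt()]).
#' @param renormalize per-step renormalization flag.
#' @return List of `distribution_field` snapshots, one per `t_point`.
#' @export
pide_solve <- function(circuit, t_points, P0 = NULL, grid = NULL, dt = NULL,
                       renormalize = TRUE) {
  validate_circuit(circuit)
  if (is.unsorted(t_points, strictly = TRUE) && length(t_points) > 1L)
    stop("t_points must be increasing")
  if (is.null(P0)) {
    if (is.null(grid)) grid <- make_grid(circuit)
    P0 <- default_p0(circuit, grid)
  }
  grid <- P0$grid
  if (is.null(dt)) dt <- pide_default_dt(circuit, grid)
  dt <- min(dt, pide_dt_stable(circuit, grid))
  ops <- pide_operators(circuit, grid, dt)
  snapshots <- vector("list", length(t_points))
  field <- P0
  for (k in seq_along(t_points)) {
    target <- t_points[k]
    if (target < field$t - 1e-12)
      stop("t_points must not precede the initial field time")
    span <- target - field$t
    if (span > 1e-12) {
      nstep <- max(1L, ceiling(span / dt - 1e-9))
      step_dt <- span / nstep
      local_ops <- if (abs(step_dt - dt) < 1e-12 * max(dt, 1)) ops
                   else pide_operators(circuit, grid, step_dt)
      for (s in seq_len(nstep))
        field <- pide_step(field, circuit, step_dt, local_ops, renormalize)
    }
    field$t <- target
    snapshots[[k]] <- field
  }
  snapshots
}

#' Stationary distribution of the PIDE
#'
#' Iterates [pide_step()] until the L1 change per unit time drops below
#' `tol`. Errors (carrying the last change rate) if `max_iter` steps do not
#' converge.
#'
#' @param circuit a `gene_circuit`.
#' @param grid grid (default [make_grid()]).
#' @param P0 initial field (default [default_p0()]).
#' @param dt time step (default [pide_default_dt()]).
#' @param tol convergence threshold on L1 change per unit time.
#' @param max_iter maximum number of steps.
#' @param check_every steps between convergence checks.
#' @return The converged `distribution_field` with attributes `iterations`
#'   and `l1_rate`.
#' @export
pide_stationary <- function(circuit, grid = NULL, P0 = NULL, dt = NULL,
                            tol = 1e-4, max_iter = 200000L,
                            check_every = 25L) {
  if (tol <= 0) stop("tol must be > 0")
  validate_circuit(circuit)
  if (is.null(P0)) {
    if (is.null(grid)) grid <- make_grid(circuit)
    P0 <- default_p0(circuit, grid)
  }
  grid <- P0$grid
  if (is.null(dt)) dt <- pide_default_dt(circuit, grid)
  dt <- min(dt, pide_dt_stable(circuit, grid))
  ops <- pide_operators(circuit, grid, dt)
  field <- P0
  iter <- 0L
  repeat {
    prev <- field$P
    for (s in seq_len(check_every))
      field <- pide_step(field, circuit, dt, ops)
    iter <- iter + check_every
    rate <- sum(abs(field$P - prev) * ops$W) / (dt * check_every)
    if (rate < tol) break
    if (iter >= max_iter)
      stop(sprintf(paste0("stationary iteration did not converge: L1 change ",
                          "per unit time %.3g > tol %.3g after %d steps"),
                   rate, tol, iter))
  }
  attr(field, "iterations") <- iter
  attr(field, "l1_rate") <- rate
  field
}

#' Marginal density of one gene
#'
#' Integrates the joint field over all other dimensions (trapezoid).
#' @param field a `distribution_field`.
#' @param gene dimension to keep.
#' @return A 1-D `distribution_field` on the gene's grid line.
#' @export
field_marginal <- function(field, gene = 1L) {
  nd <- field$grid$n_genes
  g1 <- structure(list(n_genes = 1L, n_points = field$grid$n_points[gene],
                       x_max = field$grid$x_max[gene],
                       h = field$grid$h[gene],
                       nodes = field$grid$nodes[gene]),
                  class = "pide_grid")
  if (nd == 1L)
    return(distribution_field(g1, field$P, t = field$t, normalize = FALSE))
  others <- setdiff(seq_len(nd), gene)
  Pm <- matrix(aperm(field$P, c(gene, others)),
               nrow = field$grid$n_points[gene])
  w <- as.numeric(weight_array(field$grid$nodes[others]))
  distribution_field(g1, as.numeric(Pm %*% w), t = field$t,
                     normalize = FALSE)
}

#' Aggregate a field onto histogram bins
#'
#' Exact integration of the multilinear grid interpolant over rectangular
#' bins, one set of edges per retained dimension. This is the model-to-data
#' binning used by the calibration cost.
#'
#' @param field a `distribution_field` (1-D or 2-D after marginalization).
#' @param edges list of per-dimension bin-edge vectors (or a single vector
#'   for 1-D fields).
#' @return Array of bin masses with dimension `sapply(edges, length) - 1`.
#' @export
bin_field <- function(field, edges) {
  if (!is.list(edges)) edges <- list(edges)
  nd <- field$grid$n_genes
  if (length(edges) != nd)
    stop("need one edge vector per field dimension")
  A <- lapply(seq_len(nd), function(d)
    bin_matrix(field$grid$nodes[[d]], edges[[d]]))
  P <- field$P
  for (d in seq_len(nd)) P <- apply_dim(P, d, function(Pm) A[[d]] %*% Pm)
  P
}

#' Strict local maxima of a distribution field
#'
#' Finds grid nodes whose density strictly exceeds all orthogonal neighbors
#' (boundary nodes compare only against existing neighbors), sorted by
#' decreasing density. Used for bimodality objectives.
#'
#' @param field a `distribution_field`.
#' @param min_value ignore maxima below this density (filters flat noise in
#'   empty regions).
#' @return Data frame with node indices, coordinates and density values.
#' @export
find_modes <- function(field, min_value = 0) {
  P <- field$P
  dims <- dim(P)
  nd <- length(dims)
  is_max <- P > min_value
  for (d in seq_len(nd)) {
    up <- apply_dim(P, d, function(Pm)
      rbind(Pm[-1L, , drop = FALSE], -Inf))      # neighbor at +1
    dn <- apply_dim(P, d, function(Pm)
      rbind(-Inf, Pm[-dims[d], , drop = FALSE])) # neighbor at -1
    is_max <- is_max & (P > up) & (P > dn)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (length(idx) == 0L)
    return(data.frame(value = numeric(0)))
  idx <- matrix(idx, ncol = nd)
  coords <- vapply(seq_len(nd), function(d)
    field$grid$nodes[[d]][idx[, d]], numeric(nrow(idx)))
  coords <- matrix(coords, ncol = nd)
  out <- data.frame(idx, coords, value = P[matrix(idx, ncol = nd)])
  names(out) <- c(paste0("i", seq_len(nd)), paste0("x", seq_len(nd)), "value")
  out[order(-out$value), , drop = FALSE]
}

# --- text serialization -----------------------------------------------------

#' Write a 1-D or 2-D distribution field to delimited text
#'
#' Header comments carry the grid geometry; the body holds node coordinates
#' and density values (long format for 2-D).
#' @param field a `distribution_field` (1 or 2 dimensions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  nd <- field$grid$n_genes
  if (nd > 2L) stop("text serialization covers 1-D and 2-D fields")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# stochcirc distribution field",
               paste0("# t: ", field$t),
               paste0("# n_points: ", paste(field$grid$n_points, collapse = " ")),
               paste0("# x_max: ", paste(field$grid$x_max, collapse = " "))),
             con)
  if (nd == 1L) {
    df <- data.frame(x = field$grid$nodes[[1L]], density = as.numeric(field$P))
  } else {
    df <- expand.grid(i = seq_len(field$grid$n_points[1L]),
                      j = seq_len(field$grid$n_points[2L]))
    df <- data.frame(x1 = field$grid$nodes[[1L]][df$i],
                     x2 = field$grid$nodes[[2L]][df$j],
                     density = as.numeric(field$P))
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a distribution field written by [write_field()]
#' @param path input path.
#' @return A `distribution_field`.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln), " +")[[1L]])
  }
  t0 <- get("t"); np <- as.integer(get("n_points")); xm <- get("x_max")
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  grid <- structure(list(n_genes = length(np), n_points = np, x_max = xm,
                         h = xm / (np - 1L),
                         nodes = lapply(seq_along(np), function(d)
                           seq(0, xm[d], length.out = np[d]))),
                    class = "pide_grid")
  distribution_field(grid, df$density, t = t0, normalize = FALSE)
}
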