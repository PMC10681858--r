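# Internal numerical helpers shared by the PIDE solver, binning and metrics.

#' Apply a matrix operator along one dimension of an array
#'
#' Permutes dimension `d` to the front, applies `f` to the resulting
#' (n_d x prod(other dims)) matrix and permutes back. Used for the
#' dimension-split advection/jump updates and for marginalization.
#' @noRd
apply_dim <- function(P, d, f) {
  dims <- dim(P)
  if (is.null(dims)) dims <- length(P)
  nd <- length(dims)
  if (nd == 1L) {
    out <- f(matrix(P, nrow = dims[1L]))
    return(array(out, nrow(out)))
  }
  perm <- c(d, seq_len(nd)[-d])
  Pm <- matrix(aperm(P, perm), nrow = dims[d])
  Rm <- f(Pm)
  newdims <- dims[perm]
  newdims[1L] <- nrow(Rm)
  R <- array(Rm, newdims)
  aperm(R, order(perm))
}

#' Trapezoidal quadrature weights on a uniform grid
#' @noRd
trapz_weights <- function(nodes) {
  n <- length(nodes)
  h <- nodes[2L] - nodes[1L]
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

#' Tensor product of per-dimension quadrature weights
#' @noRd
weight_array <- function(nodes_list) {
  ws <- lapply(nodes_list, trapz_weights)
  W <- ws[[1L]]
  if (length(ws) > 1L) {
    for (k in 2L:length(ws)) W <- outer(W, ws[[k]])
  }
  array(W, vapply(nodes_list, length, 1L))
}

#' Integral of the piecewise-linear hat basis function centred at `c0`
#' (half-width `h`) over the interval [lo, hi].
#'
#' Closed form used to build exact aggregation matrices taking a grid
#' interpolant to histogram-bin masses.
#' @noRd
hat_integral <- function(c0, h, lo, hi) {
  # rising branch on [c0-h, c0]: phi(x) = 1 - (c0-x)/h
  a <- pmax(lo, c0 - h); b <- pmin(hi, c0)
  rise <- ifelse(b > a, (b - a) - ((c0 - a)^2 - (c0 - b)^2) / (2 * h), 0)
  # falling branch on [c0, c0+h]: phi(x) = 1 - (x-c0)/h
  a2 <- pmax(lo, c0); b2 <- pmin(hi, c0 + h)
  fall <- ifelse(b2 > a2, (b2 - a2) - ((b2 - c0)^2 - (a2 - c0)^2) / (2 * h), 0)
  rise + fall
}

#' Aggregation matrix from grid nodes to histogram bins
#'
#' Row r, column l holds the integral over bin r of the hat function at
#' node l, so `A %*% values` is the exact mass of the grid interpolant in
#' each bin (per dimension).
#' @noRd
bin_matrix <- function(nodes, edges) {
  h <- nodes[2L] - nodes[1L]
  nb <- length(edges) - 1L
  A <- matrix(0, nb, length(nodes))
  for (r in seq_len(nb)) {
    A[r, ] <- hat_integral(nodes, h, edges[r], edges[r + 1L])
  }
  A
}

#' Clamp a vector into box bounds
#' @noRd
clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

`%||%` <- function(a, b) if (is.null(a)) b else a
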