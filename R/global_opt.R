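#' Global minimization of a box-bounded mixed-integer objective
#'
#' A compact scatter-search heuristic for MINLP problems, used by the
#' calibration and design modules. The algorithm: (a) a Latin-hypercube
#' diversification set (default `10 * dim` points, integer slots rounded);
#' (b) a reference set of `max(6, dim)` members balancing objective quality
#' and mutual diversity; (c) repeated pairwise hyper-rectangle combinations
#' with stochastic rounding of integer slots and greedy replacement of the
#' worst member; (d) stagnation-triggered regeneration of the worst half;
#' (e) a final derivative-free coordinate polish of the incumbent over the
#' real slots only (integer slots stay at their incumbent values). The evaluation
#' budget is respected exactly and the whole run is deterministic given
#' `seed`.
#'
#' Objectives that error or return non-finite values are assigned a large
#' finite penalty (1e6) and still count against the budget.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper finite bound vectors.
#' @param integer indices of integer-constrained slots (integral bounds).
#' @param budget maximum number of objective evaluations (>= 1).
#' @param seed integer seed controlling all randomness.
#' @param refset_size reference-set size (default `max(6, dim)`).
#' @param n_diverse diversification sample size (default `10 * dim`).
#' @param stagnation_limit combination rounds without improvement before the
#'   worst half of the reference set is regenerated.
#' @param local_polish run the final coordinate polish (default `TRUE`).
#' @param polish_frac fraction of the budget reserved for polishing.
#' @return An object of class `optim_result`: `par`, `value`, `n_eval`,
#'   `trace` (best-so-far value after each evaluation) and `seed`.
#' @examples
#' res <- minlp_minimize(function(x) sum(x^2), rep(-5, 3), rep(5, 3),
#'                       budget = 500, seed = 1)
#' res$value
#' @export
minlp_minimize <- function(fn, lower, upper, integer = NULL,
                           budget = 1000L, seed = 1L, refset_size = NULL,
                           n_diverse = NULL, stagnation_limit = 20L,
                           local_polish = TRUE, polish_frac = 0.3) {
  integer <- if (is.null(integer)) numeric(0) else as.numeric(integer)
  dim <- length(lower)
  stopifnot(length(upper) == dim, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  if (budget < 1) stop("budget must be >= 1")
  if (length(integer) > 0L &&
      (any(lower[integer] != round(lower[integer])) ||
       any(upper[integer] != round(upper[integer]))))
    stop("integer slots need integral bounds")
  set.seed(as.integer(seed))

  ct <- new.env(parent = emptyenv())
  ct$n <- 0L
  ct$best_x <- NULL
  ct$best_f <- Inf
  ct$trace <- numeric(budget)
  evaluate <- function(x) {
    if (ct$n >= budget) return(NA_real_)
    x <- clip_box(x, lower, upper)
    if (length(integer) > 0L) x[integer] <- round(x[integer])
    f <- tryCatch(fn(x), error = function(e) 1e6)
    if (!is.finite(f)) f <- 1e6
    ct$n <- ct$n + 1L
    if (f < ct$best_f) { ct$best_f <- f; ct$best_x <- x }
    ct$trace[ct$n] <- ct$best_f
    f
  }
  lhs_points <- function(m) {
    U <- lhs::randomLHS(m, dim)
    X <- sweep(sweep(U, 2L, upper - lower, `*`), 2L, lower, `+`)
    if (length(integer) > 0L) X[, integer] <- round(X[, integer])
    X
  }
  stoch_round <- function(z) {
    zf <- floor(z)
    zf + (stats::runif(length(z)) < (z - zf))
  }

  # (a) diversification
  n_div <- min(n_diverse %||% (10L * dim), budget)
  n_div <- max(n_div, min(budget, 2L))
  X <- lhs_points(n_div)
  fx <- apply(X, 1L, evaluate)
  keep <- !is.na(fx)
  X <- X[keep, , drop = FALSE]; fx <- fx[keep]

  main_budget <- if (local_polish) max(ct$n, floor(budget * (1 - polish_frac)))
                 else budget

  # (b) reference set: half best, half maximally diverse
  b <- min(refset_size %||% max(6L, dim), nrow(X))
  if (b >= 2L && ct$n < main_budget) {
    ord <- order(fx)
    nq <- ceiling(b / 2)
    sel <- ord[seq_len(nq)]
    rest <- setdiff(seq_len(nrow(X)), sel)
    scale <- upper - lower
    while (length(sel) < b && length(rest) > 0L) {
      dmin <- vapply(rest, function(r) {
        min(colSums((t(X[sel, , drop = FALSE]) - X[r, ])^2 / scale^2))
      }, numeric(1L))
      pick <- rest[which.max(dmin)]
      sel <- c(sel, pick)
      rest <- setdiff(rest, pick)
    }
    RX <- X[sel, , drop = FALSE]; rf <- fx[sel]

    # (c) combination rounds
    stag <- 0L
    while (ct$n < main_budget) {
      best_before <- min(rf)
      pairs <- utils::combn(seq_len(nrow(RX)), 2L)
      for (p in seq_len(ncol(pairs))) {
        if (ct$n >= main_budget) break
        xi <- RX[pairs[1L, p], ]; xj <- RX[pairs[2L, p], ]
        d <- abs(xj - xi)
        lo <- pmin(xi, xj) - 0.25 * d
        hi <- pmax(xi, xj) + 0.25 * d
        child <- lo + stats::runif(dim) * (hi - lo)
        child <- clip_box(child, lower, upper)
        if (length(integer) > 0L)
          child[integer] <- clip_box(stoch_round(child[integer]),
                                     lower[integer], upper[integer])
        # duplicate avoidance: a child identical to a RefSet member wastes
        # its evaluation, so perturb one random slot instead
        tries <- 0L
        while (any(apply(RX, 1L, function(r) all(abs(r - child) < 1e-12))) &&
               (tries <- tries + 1L) <= 20L) {
          k <- sample.int(dim, 1L)
          if (k %in% integer) {
            child[k] <- clip_box(child[k] + sample(c(-1, 1), 1L),
                                 lower[k], upper[k])
          } else {
            child[k] <- stats::runif(1L, lower[k], upper[k])
          }
        }
        f <- evaluate(child)
        if (is.na(f)) break
        worst <- which.max(rf)
        if (f < rf[worst]) { RX[worst, ] <- child; rf[worst] <- f }
      }
      if (min(rf) < best_before - 1e-15) stag <- 0L else stag <- stag + 1L
      if (stag >= stagnation_limit) {
        # regenerate the worst half from a fresh LHS draw
        nrep <- floor(nrow(RX) / 2)
        if (nrep > 0L && ct$n < main_budget) {
          Xn <- lhs_points(nrep)
          fn2 <- apply(Xn, 1L, evaluate)
          ok <- !is.na(fn2)
          if (any(ok)) {
            worst_idx <- order(rf, decreasing = TRUE)[seq_len(sum(ok))]
            RX[worst_idx, ] <- Xn[ok, , drop = FALSE]
            rf[worst_idx] <- fn2[ok]
          }
        }
        stag <- 0L
      }
    }
  }

  # (d) local polish of the incumbent with the remaining budget
  if (local_polish && ct$n < budget && !is.null(ct$best_x)) {
    coordinate_polish(evaluate, ct, lower, upper, integer,
                      max_evals = budget - ct$n)
  }

  structure(list(par = ct$best_x, value = ct$best_f, n_eval = ct$n,
                 trace = ct$trace[seq_len(ct$n)], seed = seed),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat("<optim_result> value ", format(x$value), " after ", x$n_eval,
      " evaluations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Derivative-free polish of the incumbent over the real slots only (integer
# slots stay fixed, as in the scatter-search local phase). `evaluate` must
# be the counted wrapper updating ct$best_x / ct$best_f and clipping to
# bounds; improvements are accepted greedily so the incumbent value never
# increases. One real slot uses a shrinking-step line search; two or more
# use restarted Nelder-Mead simplices (which track the correlated valleys
# that coordinate moves zigzag across).
coordinate_polish <- function(evaluate, ct, lower, upper, integer,
                              max_evals) {
  start <- ct$n
  dim <- length(ct$best_x)
  real_idx <- setdiff(seq_len(dim), integer)
  if (length(real_idx) == 0L || max_evals < 1L) return(invisible(NULL))

  if (length(real_idx) == 1L) {
    x <- ct$best_x
    fbest <- ct$best_f
    k <- real_idx
    step <- 0.25 * (upper[k] - lower[k])
    repeat {
      improved <- FALSE
      for (s in c(+1, -1)) {
        if (ct$n - start >= max_evals) return(invisible(NULL))
        cand <- x
        cand[k] <- cand[k] + s * step
        if (cand[k] < lower[k] || cand[k] > upper[k]) next
        f <- evaluate(cand)
        if (is.na(f)) return(invisible(NULL))
        if (f < fbest - 1e-15) {
          x <- cand; fbest <- f; improved <- TRUE
          break
        }
      }
      if (!improved) {
        if (step <= 1e-10 * (upper[k] - lower[k])) return(invisible(NULL))
        step <- step / 2
      }
    }
  }

  repeat {
    prev_best <- ct$best_f
    x0 <- ct$best_x
    nm_fn <- function(xr) {
      if (ct$n - start >= max_evals) return(1e12)
      x <- x0
      x[real_idx] <- xr
      f <- evaluate(x)
      if (is.na(f)) 1e12 else f
    }
    suppressWarnings(stats::optim(
      x0[real_idx], nm_fn, method = "Nelder-Mead",
      control = list(maxit = 200L * length(real_idx), reltol = 1e-14,
                     warn.1d.NelderMead = FALSE)))
    if (ct$n - start >= max_evals || ct$best_f >= prev_best - 1e-14)
      return(invisible(NULL))
  }
}

#' Derivative-free local refinement within bounds
#'
#' Standalone coordinate search used as the scatter search's local phase:
#' real slots are refined with shrinking steps while integer slots are left
#' unchanged. Never returns a point worse than `x0`; with `max_evals = 0`
#' returns `x0` unchanged.
#'
#' @param fn objective function.
#' @param x0 feasible starting point.
#' @param lower,upper bounds.
#' @param integer indices of integer slots.
#' @param max_evals evaluation cap.
#' @return List with `par`, `value` (`fn(x0)` is evaluated once, not counted
#'   against `max_evals`) and `n_eval`.
#' @export
local_polish <- function(fn, x0, lower, upper, integer = NULL,
                         max_evals = 100L) {
  integer <- if (is.null(integer)) numeric(0) else as.numeric(integer)
  if (any(x0 < lower) || any(x0 > upper)) stop("x0 must lie within bounds")
  ct <- new.env(parent = emptyenv())
  ct$n <- 0L
  ct$best_x <- x0
  f0 <- tryCatch(fn(x0), error = function(e) 1e6)
  if (!is.finite(f0)) f0 <- 1e6
  ct$best_f <- f0
  if (max_evals > 0L) {
    evaluate <- function(x) {
      if (ct$n >= max_evals) return(NA_real_)
      x <- clip_box(x, lower, upper)
      f <- tryCatch(fn(x), error = function(e) 1e6)
      if (!is.finite(f)) f <- 1e6
      ct$n <- ct$n + 1L
      if (f < ct$best_f) { ct$best_f <- f; ct$best_x <- x }
      f
    }
    coordinate_polish(evaluate, ct, lower, upper, integer, max_evals)
  }
  list(par = ct$best_x, value = ct$best_f, n_eval = ct$n)
}
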