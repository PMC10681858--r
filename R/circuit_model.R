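#' Construct a gene regulatory circuit
#'
#' A circuit couples a regulatory topology with the kinetic parameters of the
#' standard four-reaction gene expression network (transcription, translation,
#' mRNA degradation, protein degradation; one block per gene). The topology is
#' an `n_genes x n_genes` integer matrix `T` with `T[i, j] = +1` if protein
#' `j` activates gene `i`, `-1` if it represses it and `0` for no regulation.
#' Each nonzero entry carries a Hill regulation threshold `K[i, j]` (molecules)
#' and cooperativity `n_hill[i, j] >= 1`.
#'
#' Promoter activity of gene `i` is the leaky product-of-Hills input function
#' \deqn{c_i(x) = \epsilon_i + (1-\epsilon_i)\prod_{j: T_{ij}\neq 0} h_{ij}(x_j)}
#' with \eqn{h_{ij}} the increasing (activation) or decreasing (repression)
#' Hill term. Genes without regulators have \eqn{c_i = 1}.
#'
#' @param topology integer matrix with entries in \{-1, 0, 1\}.
#' @param km,kx,gm,gx per-gene transcription (molecules/time), translation
#'   (1/time), mRNA degradation (1/time) and protein degradation (1/time)
#'   rate constants; scalars are recycled.
#' @param eps per-gene promoter leakage in `[0, 1)` (basal activity of a fully
#'   repressed promoter).
#' @param K,n_hill matrices of regulation thresholds (> 0, molecules) and Hill
#'   coefficients (>= 1); only entries at nonzero topology positions are used
#'   and all such entries must be present (non-`NA`).
#' @param names optional character vector of gene labels.
#' @return An object of class `gene_circuit`.
#' @examples
#' toggle <- gene_circuit(
#'   topology = matrix(c(0, -1, -1, 0), 2, 2, byrow = TRUE),
#'   km = 4, kx = 50, gm = 10, gx = 1, eps = 0.02,
#'   K = matrix(c(NA, 6, 6, NA), 2, 2), n_hill = matrix(c(NA, 2, 2, NA), 2, 2)
#' )
#' evaluate_input(toggle, c(0, 25))
#' @export
gene_circuit <- function(topology, km, kx, gm, gx, eps = 0,
                         K = NULL, n_hill = NULL, names = NULL) {
  topology <- as.matrix(topology)
  storage.mode(topology) <- "integer"
  n <- nrow(topology)
  rec <- function(v) {
    v <- as.numeric(v)
    if (length(v) == 1L) rep(v, n) else v
  }
  if (is.null(K)) K <- matrix(NA_real_, n, n)
  if (is.null(n_hill)) n_hill <- matrix(NA_real_, n, n)
  circuit <- structure(list(
    n_genes = n,
    topology = topology,
    km = rec(km), kx = rec(kx), gm = rec(gm), gx = rec(gx), eps = rec(eps),
    K = as.matrix(K) * 1.0, n_hill = as.matrix(n_hill) * 1.0,
    names = names
  ), class = "gene_circuit")
  validate_circuit(circuit)
}

#' Validate a gene circuit
#'
#' Checks all structural invariants: square \{-1,0,1\} topology, strictly
#' positive rates, leakage in `[0, 1)`, and an edge-parameter set (`K`,
#' `n_hill`) that matches the nonzero topology entries exactly. Errors name
#' the offending field.
#'
#' @param circuit a `gene_circuit`.
#' @return The circuit, invisibly usable in pipelines (returned visibly).
#' @export
validate_circuit <- function(circuit) {
  n <- circuit$n_genes
  T0 <- circuit$topology
  if (!is.matrix(T0) || nrow(T0) != n || ncol(T0) != n)
    stop("topology: must be a square ", n, " x ", n, " matrix")
  if (!all(T0 %in% c(-1L, 0L, 1L)))
    stop("topology: entries must be in {-1, 0, +1}")
  for (nm in c("km", "kx", "gm", "gx", "eps")) {
    v <- circuit[[nm]]
    if (length(v) != n || !is.numeric(v) || anyNA(v))
      stop(nm, ": needs one finite value per gene")
    if (nm != "eps" && any(v <= 0))
      stop(nm, ": rate constants must be strictly positive")
  }
  if (any(circuit$eps < 0 | circuit$eps >= 1))
    stop("eps: promoter leakage must lie in [0, 1)")
  edges <- which(T0 != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    Kij <- circuit$K[i, j]; nij <- circuit$n_hill[i, j]
    key <- paste0("[", i, ",", j, "]")
    if (is.na(Kij) || is.na(nij))
      stop("edge ", key, ": regulation parameters K and n_hill are required ",
           "for every nonzero topology entry")
    if (Kij <= 0) stop("K", key, ": threshold must be > 0")
    if (nij < 1) stop("n_hill", key, ": cooperativity must be >= 1")
  }
  # parameters must not claim edges the topology does not have
  extra <- which((!is.na(circuit$K) | !is.na(circuit$n_hill)) & T0 == 0L,
                 arr.ind = TRUE)
  if (nrow(extra) > 0L)
    stop("edge [", extra[1L, 1L], ",", extra[1L, 2L],
         "]: K/n_hill given but topology entry is 0")
  if (!is.null(circuit$names) && length(circuit$names) != n)
    stop("names: needs one label per gene")
  circuit
}

#' @export
print.gene_circuit <- function(x, ...) {
  cat("<gene_circuit> ", x$n_genes, " gene(s)\n", sep = "")
  nm <- x$names %||% paste0("g", seq_len(x$n_genes))
  dimnames(x$topology) <- list(nm, nm)
  cat("topology (rows = target gene, cols = regulator):\n")
  print(x$topology)
  rates <- data.frame(gene = nm, km = x$km, kx = x$kx, gm = x$gm,
                      gx = x$gx, eps = x$eps, b = burst_sizes(x))
  print(rates, row.names = FALSE)
  invisible(x)
}

#' Mean translational burst sizes
#'
#' The mean number of proteins produced per mRNA lifetime, `b_i = kx_i/gm_i`.
#' This is the mean of the exponential burst kernel used by the PIDE model.
#' @param circuit a `gene_circuit`.
#' @return Numeric vector of per-gene burst sizes.
#' @export
burst_sizes <- function(circuit) circuit$kx / circuit$gm

#' Evaluate the promoter input functions
#'
#' Returns the dimensionless promoter activities `c_i(x)` in
#' `[eps_i, 1]` for a vector of protein levels, using the leaky
#' product-of-Hills form (see [gene_circuit()]). Unregulated genes return 1
#' (empty product).
#'
#' @param circuit a `gene_circuit`.
#' @param x nonnegative protein-level vector of length `n_genes`.
#' @return Numeric vector `c` with `eps <= c <= 1`.
#' @export
evaluate_input <- function(circuit, x) {
  if (length(x) != circuit$n_genes)
    stop("x must have one protein level per gene")
  if (any(x < 0)) stop("protein levels must be nonnegative")
  vapply(seq_len(circuit$n_genes), function(i) {
    evaluate_input_gene(circuit, i, lapply(seq_len(circuit$n_genes),
                                           function(j) x[j]))[1L]
  }, numeric(1L))
}

#' Promoter activity of one gene on a tensor grid of regulator levels
#'
#' Evaluates `c_i` over the tensor grid spanned by per-gene coordinate
#' vectors, returning an array with one dimension per gene. With scalar
#' coordinates this reduces to a single value; the PIDE solver uses the full
#' grid form. `hill_override` allows registering an alternative per-edge
#' response family (a function of `(x, K, n, sign)` returning values in
#' `[0, 1]`), keeping the input-function family pluggable.
#'
#' @param circuit a `gene_circuit`.
#' @param i target gene index.
#' @param coords list of `n_genes` nonnegative coordinate vectors.
#' @param hill_override optional replacement for the Hill edge response.
#' @return Array of dimension `lengths(coords)` (dropped to a vector in 1-D).
#' @export
evaluate_input_gene <- function(circuit, i, coords, hill_override = NULL) {
  if (any(vapply(coords, function(v) any(v < 0), logical(1L))))
    stop("protein levels must be nonnegative")
  dims <- vapply(coords, length, 1L)
  prod_arr <- array(1, dims)
  hill <- hill_override %||% function(x, K, n, sign) {
    xn <- x^n; Kn <- K^n
    if (sign > 0) xn / (Kn + xn) else Kn / (Kn + xn)
  }
  for (j in which(circuit$topology[i, ] != 0L)) {
    hv <- hill(coords[[j]], circuit$K[i, j], circuit$n_hill[i, j],
               circuit$topology[i, j])
    prod_arr <- if (length(dims) == 1L) prod_arr * hv
    else sweep(prod_arr, j, hv, `*`)
  }
  circuit$eps[i] + (1 - circuit$eps[i]) * prod_arr
}

#' Reaction propensities of the circuit
#'
#' Evaluates the propensity vector of the `4 * n_genes` reactions, ordered
#' per gene `i` as: transcription `km_i * c_i(X)`, translation
#' `kx_i * mRNA_i`, mRNA degradation `gm_i * mRNA_i`, protein degradation
#' `gx_i * X_i`.
#'
#' @param circuit a `gene_circuit`.
#' @param mrna,protein nonnegative integer copy-number vectors.
#' @return Numeric vector of length `4 * n_genes`.
#' @seealso [stoich_matrix()] for the matching stoichiometry.
#' @export
propensities <- function(circuit, mrna, protein) {
  if (any(mrna < 0) || any(protein < 0))
    stop("copy numbers must be nonnegative")
  cc <- evaluate_input(circuit, protein)
  a <- rbind(circuit$km * cc, circuit$kx * mrna,
             circuit$gm * mrna, circuit$gx * protein)
  as.numeric(a)
}

#' Stoichiometry matrix of the circuit reactions
#'
#' One row per reaction (ordered as in [propensities()]), one column per
#' species, species ordered `mRNA_1..n, X_1..n`. Every row changes exactly
#' one species by +/-1.
#'
#' @param circuit a `gene_circuit`.
#' @return Integer matrix of dimension `4*n_genes x 2*n_genes`.
#' @export
stoich_matrix <- function(circuit) {
  n <- circuit$n_genes
  S <- matrix(0L, 4L * n, 2L * n)
  for (i in seq_len(n)) {
    r <- 4L * (i - 1L)
    S[r + 1L, i] <- 1L        # transcription: mRNA_i + 1
    S[r + 2L, n + i] <- 1L    # translation:   X_i + 1
    S[r + 3L, i] <- -1L       # mRNA decay:    mRNA_i - 1
    S[r + 4L, n + i] <- -1L   # protein decay: X_i - 1
  }
  S
}

# ---------------------------------------------------------------------------
# Serialization: one structured-config (YAML) schema is the only ingestion path

#' Read a circuit configuration file
#'
#' The YAML schema has keys `n_genes`, `topology` (list of rows), `genes`
#' (list of `{km, kx, gm, gx, eps}` blocks) and `edges` (list of
#' `{i, j, K, n}` blocks, `i` = target gene, `j` = regulator, 1-based).
#' All circuit invariants are validated on load and errors name the
#' offending key.
#'
#' @param path file path.
#' @return A validated `gene_circuit`.
#' @export
read_circuit <- function(path) {
  if (!file.exists(path)) stop("circuit config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("n_genes", "topology", "genes"))
    if (is.null(cfg[[key]])) stop("circuit config: missing key '", key, "'")
  n <- as.integer(cfg$n_genes)
  T0 <- do.call(rbind, lapply(cfg$topology, as.integer))
  if (length(cfg$genes) != n)
    stop("circuit config: 'genes' must list ", n, " blocks")
  g <- function(field) vapply(cfg$genes, function(b) {
    if (is.null(b[[field]])) stop("circuit config: gene block missing '",
                                  field, "'")
    as.numeric(b[[field]])
  }, numeric(1L))
  K <- matrix(NA_real_, n, n); nh <- matrix(NA_real_, n, n)
  for (e in cfg$edges %||% list()) {
    # YAML 1.1 resolves a bare `n` key to boolean FALSE; recover it
    names(e)[names(e) == "FALSE"] <- "n"
    if (is.null(e$i) || is.null(e$j) || is.null(e$K) || is.null(e$n))
      stop("circuit config: edge blocks need keys i, j, K, n")
    K[e$i, e$j] <- as.numeric(e$K)
    nh[e$i, e$j] <- as.numeric(e$n)
  }
  gene_circuit(T0, km = g("km"), kx = g("kx"), gm = g("gm"), gx = g("gx"),
               eps = vapply(cfg$genes, function(b) as.numeric(b$eps %||% 0),
                            numeric(1L)),
               K = K, n_hill = nh,
               names = unlist(cfg$names) %||% NULL)
}

#' Write a circuit configuration file
#'
#' Inverse of [read_circuit()]; round-trips all fields.
#' @param circuit a `gene_circuit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(circuit, path) {
  n <- circuit$n_genes
  edges <- which(circuit$topology != 0L, arr.ind = TRUE)
  cfg <- list(
    n_genes = n,
    names = circuit$names,
    topology = lapply(seq_len(n), function(i) as.integer(circuit$topology[i, ])),
    genes = lapply(seq_len(n), function(i) list(
      km = circuit$km[i], kx = circuit$kx[i], gm = circuit$gm[i],
      gx = circuit$gx[i], eps = circuit$eps[i])),
    edges = lapply(seq_len(nrow(edges)), function(r) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      list(i = i, j = j, K = circuit$K[i, j], n = circuit$n_hill[i, j])
    })
  )
  if (is.null(cfg$names)) cfg$names <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}
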