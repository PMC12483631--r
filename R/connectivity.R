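#' Construct a point cloud
#'
#' A point cloud is the basic geometric input: `N` nodes in `n`-dimensional
#' space (arbitrary length units).  Coordinates must be finite and share one
#' dimension.
#'
#' @param coords numeric matrix, one node per row.
#' @param ids optional node identifiers (defaults to `1:N`).
#' @return an object of class `point_cloud` with elements `coords` and `ids`.
#' @export
point_cloud <- function(coords, ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop("a point cloud needs at least one node")
  bad <- which(!apply(coords, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite coordinates at node(s): ", paste(bad, collapse = ", "))
  ids <- ids %||% seq_len(nrow(coords))
  if (length(ids) != nrow(coords)) stop("ids must match the number of nodes")
  structure(list(coords = coords, ids = ids), class = "point_cloud")
}

#' Read a point cloud from delimited text
#'
#' Whitespace- or comma-delimited text, one node per line, 2-3 coordinate
#' columns, with an optional leading id column.
#'
#' @param path file path.
#' @param has_ids does the first column hold node identifiers?
#' @param sep field separator passed to [read.table()] (`""` = whitespace).
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, has_ids = FALSE, sep = "") {
  tab <- read.table(path, header = FALSE, sep = sep,
                    stringsAsFactors = FALSE)
  if (has_ids) {
    point_cloud(as.matrix(tab[, -1L, drop = FALSE]), ids = tab[[1L]])
  } else {
    point_cloud(as.matrix(tab))
  }
}

#' Euclidean pairwise distances between nodes
#'
#' @param cloud a [point_cloud()] or a bare coordinate matrix.
#' @return symmetric `N x N` matrix with zero diagonal, in the units of the
#'   input coordinates.
#' @export
pairwise_distances <- function(cloud) {
  if (!inherits(cloud, "point_cloud")) cloud <- point_cloud(cloud)
  d <- as.matrix(dist(cloud$coords))
  dimnames(d) <- NULL
  diag(d) <- 0
  d
}

#' Kernel specification for distance-based connectivity
#'
#' Three monotonically decreasing kernel families map distance to coupling
#' weight: a hard `cutoff` at the characteristic distance `sigma`, a
#' generalized exponential `exp(-d^kappa / (kappa * sigma^kappa))`, and a
#' power law `(d / sigma)^(-nu)`.  One global `sigma` is used for all pairs.
#'
#' @param family one of `"exponential"`, `"cutoff"`, `"power"`.
#' @param sigma characteristic distance, `> 0` (same units as the input
#'   coordinates).  Default 3.
#' @param kappa positive-integer exponential order (default 1, plain
#'   exponential decay `exp(-d/sigma)`).
#' @param nu power-law exponent, `> 1`.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("exponential", "cutoff", "power"),
                        sigma = 3, kappa = 1L, nu = 3) {
  family <- match.arg(family)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (family == "exponential" &&
      (kappa < 1 || kappa != round(kappa)))
    stop("kappa must be a positive integer")
  if (family == "power" && nu <= 1) stop("nu must be > 1")
  structure(list(family = family, sigma = sigma, kappa = as.integer(kappa),
                 nu = nu), class = "kernel_spec")
}

new_connectivity <- function(a, kernel) {
  a <- unname(a)
  diag(a) <- 0
  diag(a) <- -rowSums(a)
  structure(a, kernel = kernel, class = c("connectivity_matrix", "matrix"))
}

#' Distance-kernel connectivity matrix
#'
#' Off-diagonal entries are the kernel weights `A_ij` of the selected family;
#' every diagonal entry is minus the sum of its row's off-diagonal entries,
#' so rows sum to zero (the diffusive-coupling convention: identical states
#' experience no coupling).
#'
#' @param d a distance matrix from [pairwise_distances()].
#' @param kernel a [kernel_spec()].
#' @return a symmetric zero-row-sum `connectivity_matrix` with off-diagonal
#'   entries in `[0, 1]` for the cutoff/exponential families.
#' @export
build_connectivity <- function(d, kernel = kernel_spec()) {
  stopifnot(inherits(kernel, "kernel_spec"))
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  off <- row(d) != col(d)
  a <- matrix(0, nrow(d), ncol(d))
  if (kernel$family == "cutoff") {
    a[off] <- as.numeric(d[off] <= kernel$sigma)
  } else if (kernel$family == "exponential") {
    k <- kernel$kappa
    a[off] <- exp(-(d[off]^k) / (k * kernel$sigma^k))
  } else {
    if (any(d[off] == 0))
      stop("power-law kernel undefined at zero distance (coincident nodes)")
    a[off] <- (d[off] / kernel$sigma)^(-kernel$nu)
  }
  new_connectivity(a, kernel)
}

#' Correlation-based connectivity for multichannel signals
#'
#' Couples channels by the absolute Pearson correlation of their time
#' courses; the diagonal is minus the row sum so the matrix is a valid
#' diffusive coupling.  Pearson correlations can be negative; coupling
#' strength is non-negative, so the absolute value is taken by default, with
#' `signed = TRUE` preserving raw values for sensitivity analysis.
#'
#' @param signals numeric matrix, `N` channels x `T` samples (one channel per
#'   row), `T >= 3`.
#' @param signed keep the sign of the correlation?
#' @return a `connectivity_matrix` with `attr(., "kernel") == "correlation"`.
#' @export
correlation_connectivity <- function(signals, signed = FALSE) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 3L) stop("need at least 3 samples per channel")
  v <- apply(signals, 1L, var)
  if (any(v == 0 | !is.finite(v)))
    stop("zero-variance channel(s): ",
         paste(which(v == 0 | !is.finite(v)), collapse = ", "))
  r <- cor(t(signals))
  if (!signed) r <- abs(r)
  new_connectivity(r, "correlation")
}

#' Laplacian filtration of a weighted connectivity matrix
#'
#' Thresholds the off-diagonal weights `l_ij` at `p` evenly spaced levels
#' between their minimum and maximum.  At scale `k` (k = 1..p) an edge
#' survives only if `l_ij > (k/p) * (lmax - lmin) + lmin`; surviving
#' off-diagonals are set to -1 and each diagonal to minus its row sum, giving
#' a nested family of binarised graph Laplacians `L_1 .. L_p` (edge sets
#' shrink as `k` grows; `L_p` is always empty since the threshold reaches
#' `lmax` and ties drop the edge).
#'
#' @param a a `connectivity_matrix` (or any symmetric weight matrix whose
#'   off-diagonal entries are the weights).
#' @param p number of scales, `>= 1` (default 10).
#' @return an object of class `laplacian_family`: list with `laplacians`
#'   (list of `p` integer matrices), `thresholds`, `p`, `lmin`, `lmax`,
#'   `d_range`.
#' @export
laplacian_filtration <- function(a, p = 10L) {
  a <- as.matrix(a)
  n <- nrow(a)
  if (n < 2L) stop("Laplacian filtration needs at least 2 nodes")
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1")
  off <- row(a) != col(a)
  w <- a[off]
  lmax <- max(w); lmin <- min(w); drange <- lmax - lmin
  thresholds <- (seq_len(p) / p) * drange + lmin
  if (drange == 0)
    warning("all off-diagonal weights identical; family is all-empty")
  laps <- lapply(thresholds, function(th) {
    l <- matrix(0L, n, n)
    keep <- off & (a > th)
    l[keep] <- -1L
    diag(l) <- -as.integer(rowSums(l))
    l
  })
  structure(list(laplacians = laps, thresholds = thresholds, p = p,
                 lmin = lmin, lmax = lmax, d_range = drange),
            class = "laplacian_family")
}

#' Coupling matrix of one filtration scale
#'
#' The flow uses diffusive coupling with positive off-diagonal conductances,
#' i.e. `C = -L_k` for a filtered scale (off-diagonals +1, zero row sums).
#'
#' @param family a [laplacian_filtration()] result.
#' @param k scale index in `1..p`.
#' @return numeric coupling matrix.
#' @export
scale_coupling <- function(family, k) {
  stopifnot(inherits(family, "laplacian_family"))
  k <- as.integer(k)
  if (k < 1L || k > family$p) stop("scale index out of range")
  -family$laplacians[[k]]
}

#' @export
print.laplacian_family <- function(x, ...) {
  ne <- vapply(x$laplacians, function(l) sum(l[upper.tri(l)] != 0), 0L)
  cat("Laplacian filtration family: ", x$p, " scales, ",
      nrow(x$laplacians[[1L]]), " nodes\n", sep = "")
  cat("  weight range [", format(x$lmin), ", ", format(x$lmax), "]\n",
      sep = "")
  cat("  edges per scale:", paste(ne, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  k <- attr(x, "kernel")
  lab <- if (is.character(k)) k else
    sprintf("%s kernel (sigma=%g)", k$family, k$sigma)
  cat("Connectivity matrix: ", nrow(x), " nodes, ", lab, "\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

# Upper-triangle edge list of a symmetric coupling matrix (used by the
# compiled integrator).
coupling_edges <- function(C, drop_below = 0) {
  C <- as.matrix(C)
  ut <- upper.tri(C)
  keep <- ut & (abs(C) > drop_below)
  idx <- which(keep, arr.ind = TRUE)
  list(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L, w = C[keep])
}
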