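#' Vietoris-Rips filtration of a point cloud
#'
#' Enumerates all simplices up to `max_dim` whose birth value does not exceed
#' `alpha_max`.  A simplex on vertex set `S` is born when the growing balls
#' around its vertices pairwise intersect: under the default radius
#' convention the birth value is `max(pairwise distance in S) / 2` (an edge
#' between nodes at distance 2 is born at alpha = 1); the diameter convention
#' uses the max pairwise distance itself.
#'
#' @param d distance matrix from [pairwise_distances()].
#' @param alpha_max largest filtration value retained, `> 0`.
#' @param max_dim highest simplex dimension, in `{1, 2, 3}` (full
#'   enumeration of vertex subsets is combinatorial; raise
#'   `allow_high_dim = TRUE` to override the guard).
#' @param convention `"radius"` (default) or `"diameter"`.
#' @param allow_high_dim disable the `max_dim <= 3` guard.
#' @return object of class `simplicial_filtration`: `n_vertices`, parallel
#'   vectors `dim` and `birth`, and `verts` (list of sorted vertex tuples),
#'   sorted by (birth, dimension, lexicographic tuple).
#' @export
vietoris_rips <- function(d, alpha_max, max_dim = 2L,
                          convention = c("radius", "diameter"),
                          allow_high_dim = FALSE) {
  convention <- match.arg(convention)
  d <- as.matrix(d)
  n <- nrow(d)
  max_dim <- as.integer(max_dim)
  if (!is.finite(alpha_max) || alpha_max <= 0) stop("alpha_max must be > 0")
  if (max_dim < 1L) stop("max_dim must be >= 1")
  if (max_dim > 3L && !allow_high_dim)
    stop("max_dim > 3 disabled (combinatorial blow-up); ",
         "set allow_high_dim = TRUE to override")
  scale <- if (convention == "radius") 0.5 else 1
  dims <- integer(0); births <- numeric(0); verts <- list()
  # vertices are all born at 0
  dims <- rep(0L, n); births <- rep(0, n)
  verts <- lapply(seq_len(n), identity)
  for (q in seq_len(max_dim)) {
    if (n < q + 1L) break
    combs <- combn(n, q + 1L)
    b <- apply(combs, 2L, function(v) max(d[v, v])) * scale
    keep <- b <= alpha_max
    if (any(keep)) {
      dims <- c(dims, rep(q, sum(keep)))
      births <- c(births, b[keep])
      verts <- c(verts, lapply(which(keep), function(ci) combs[, ci]))
    }
  }
  keys <- vapply(verts, function(v)
    paste(formatC(v, width = 6, flag = "0"), collapse = ","), "")
  ord <- order(births, dims, keys)
  structure(list(n_vertices = n, dim = dims[ord], birth = births[ord],
                 verts = verts[ord], max_dim = max_dim,
                 convention = convention),
            class = "simplicial_filtration")
}

#' @export
print.simplicial_filtration <- function(x, ...) {
  cat("Vietoris-Rips filtration:", x$n_vertices, "vertices,",
      length(x$dim), "simplices up to dim", x$max_dim, "\n")
  for (q in 0:max(x$dim))
    cat("  dim", q, ":", sum(x$dim == q), "simplices\n")
  invisible(x)
}

#' Export a filtration as a plain-text simplex list
#'
#' One simplex per line: `dim birth v0 v1 ...`.
#'
#' @param f a [vietoris_rips()] filtration.
#' @param path output file.
#' @export
write_filtration <- function(f, path) {
  lines <- vapply(seq_along(f$dim), function(i)
    paste(f$dim[i], format(f$birth[i], digits = 12),
          paste(f$verts[[i]], collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}

# indices (into f$verts) of the q-simplices present at filtration value t
simplices_at <- function(f, t, q) which(f$dim == q & f$birth <= t)

simplex_key <- function(v) paste(v, collapse = ",")

#' Boundary matrix of the complex at filtration value t
#'
#' Entry for (face, simplex) is `(-1)^i` where `i` is the (0-based) index of
#' the vertex removed from the sorted tuple.  `B_0` maps onto the zero space
#' and is represented by a 0-row matrix.
#'
#' @param f a [vietoris_rips()] filtration.
#' @param t filtration value.
#' @param q order, `>= 0`.
#' @return integer matrix over \{-1, 0, 1\}; rows indexed by the
#'   `(q-1)`-simplices of `K_t`, columns by its `q`-simplices.  Row/column
#'   simplex indices are attached as attributes `rows` and `cols`.
#' @export
boundary_matrix <- function(f, t, q) {
  stopifnot(inherits(f, "simplicial_filtration"))
  q <- as.integer(q)
  if (q < 0L) stop("q must be >= 0")
  if (q > f$max_dim + 1L) stop("q exceeds max_dim + 1 of the filtration")
  cols <- simplices_at(f, t, q)
  if (q == 0L) {
    b <- matrix(0L, nrow = 0L, ncol = length(cols))
    attr(b, "rows") <- integer(0); attr(b, "cols") <- cols
    return(b)
  }
  rows <- simplices_at(f, t, q - 1L)
  rowmap <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(rows))
    assign(simplex_key(f$verts[[rows[k]]]), k, envir = rowmap)
  b <- matrix(0L, nrow = length(rows), ncol = length(cols))
  for (k in seq_along(cols)) {
    v <- f$verts[[cols[k]]]
    for (i in seq_along(v)) {
      face <- v[-i]
      ri <- get(simplex_key(face), envir = rowmap)
      b[ri, k] <- if (i %% 2L == 1L) 1L else -1L  # (-1)^(i-1), 0-based (-1)^i
    }
  }
  attr(b, "rows") <- rows; attr(b, "cols") <- cols
  b
}

# Orthonormal null-space basis of M (columns), floating point.
null_basis <- function(M) {
  if (ncol(M) == 0L) return(matrix(0, nrow = 0L, ncol = 0L))
  if (nrow(M) == 0L) return(diag(ncol(M)))
  s <- svd(M, nu = 0, nv = ncol(M))  # full V: null space of a wide matrix
  tol <- max(dim(M)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  if (r == ncol(M)) return(matrix(0, nrow = ncol(M), ncol = 0L))
  s$v[, seq.int(r + 1L, ncol(M)), drop = FALSE]
}

#' Persistent boundary operator between two filtration values
#'
#' Restricts the boundary operator of `K_{t+p}` to the q-chains whose
#' boundary lies in the span of the `(q-1)`-simplices already present in
#' `K_t`, and expresses it against those simplices.  The constrained chain
#' subspace is obtained as the null space of the rows of the boundary matrix
#' lying outside `K_t`.
#'
#' @param f a [vietoris_rips()] filtration.
#' @param t,t_plus_p filtration values with `t <= t_plus_p`.
#' @param q order, `>= 0`.
#' @return numeric matrix; rows indexed by the `(q-1)`-simplices of `K_t`,
#'   columns by an (orthonormal) basis of the constrained subspace.
#' @export
persistent_boundary <- function(f, t, t_plus_p, q) {
  if (t_plus_p < t) stop("t_plus_p must be >= t")
  D <- boundary_matrix(f, t_plus_p, q)
  if (q == 0L) return(D)  # zero-row convention: full chain space, zero map
  rows <- attr(D, "rows")
  inside <- f$birth[rows] <= t
  Dout <- D[!inside, , drop = FALSE]
  Z <- null_basis(Dout)
  res <- D[inside, , drop = FALSE] %*% Z
  attr(res, "rows") <- rows[inside]
  res
}

#' Persistent Laplacian at a pair of filtration values
#'
#' Forms `L = B %*% t(B) + t(B_q) %*% B_q` where `B` is the persistent
#' boundary operator of order `q+1` between `t` and `t_plus_p` and `B_q` the
#' ordinary boundary operator of `K_t`; for `q = 0` the second term is the
#' zero matrix.  The matrix acts on the `q`-simplices of `K_t`, is symmetric
#' positive semidefinite, and the multiplicity of its (numerically) zero
#' eigenvalues is the persistent Betti number: the count of q-dimensional
#' features of `K_t` still alive in `K_{t+p}`.  For `t == t_plus_p` it
#' reduces to the combinatorial Hodge Laplacian of `K_t`.
#'
#' @inheritParams persistent_boundary
#' @param tol_factor zero-eigenvalue tolerance is
#'   `tol_factor * (1 + largest eigenvalue)` (scale-invariant kernel
#'   detection).
#' @return object of class `pl_result`: `matrix`, sorted `eigenvalues`,
#'   `betti`, `lambda_min_nonzero` (0 when no eigenvalue clears the
#'   tolerance), and bookkeeping fields `q`, `t`, `t_plus_p`, `n_simplices`.
#' @export
persistent_laplacian <- function(f, t, t_plus_p = t, q = 0L,
                                 tol_factor = 1e-8) {
  q <- as.integer(q)
  nq <- length(simplices_at(f, t, q))
  if (nq == 0L) {
    return(structure(list(matrix = matrix(0, 0L, 0L),
                          eigenvalues = numeric(0), betti = 0L,
                          lambda_min_nonzero = 0, q = q, t = t,
                          t_plus_p = t_plus_p, n_simplices = 0L),
                     class = "pl_result"))
  }
  up <- if (q + 1L <= f$max_dim) {
    B1 <- persistent_boundary(f, t, t_plus_p, q + 1L)
    B1 %*% t(B1)
  } else {
    matrix(0, nq, nq)
  }
  down <- if (q >= 1L) {
    Bq <- boundary_matrix(f, t, q)
    crossprod(Bq)
  } else {
    matrix(0, nq, nq)
  }
  L <- up + down
  ev <- sort(eigen((L + t(L)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  tol <- tol_factor * (1 + max(ev, 0))
  betti <- sum(ev < tol)
  nz <- ev[ev >= tol]
  structure(list(matrix = L, eigenvalues = ev, betti = as.integer(betti),
                 lambda_min_nonzero = if (length(nz)) nz[1L] else 0,
                 q = q, t = t, t_plus_p = t_plus_p, n_simplices = nq),
            class = "pl_result")
}

#' @export
print.pl_result <- function(x, ...) {
  cat(sprintf(
    "Persistent Laplacian q=%d, t=%g, t+p=%g: %d simplices, betti=%d, lambda=%g\n",
    x$q, x$t, x$t_plus_p, x$n_simplices, x$betti, x$lambda_min_nonzero))
  invisible(x)
}

#' Persistent Betti numbers and spectral gaps along a filtration grid
#'
#' Sweeps `alpha_grid` and records, for each order in `q_list`, the Betti
#' number and the smallest nonzero persistent-Laplacian eigenvalue of the
#' complex at that value (p = 0, i.e. `t = t + p`).
#'
#' @param f a [vietoris_rips()] filtration.
#' @param q_list orders to track (default `c(0, 1)`).
#' @param alpha_grid increasing vector of filtration values.
#' @return data frame with columns `alpha`, `q`, `betti`, `lambda`.
#' @export
spectral_curves <- function(f, q_list = c(0L, 1L), alpha_grid) {
  if (is.unsorted(alpha_grid, strictly = FALSE))
    stop("alpha_grid must be increasing")
  rows <- lapply(alpha_grid, function(a) {
    do.call(rbind, lapply(q_list, function(q) {
      r <- persistent_laplacian(f, a, a, q)
      data.frame(alpha = a, q = q, betti = r$betti,
                 lambda = r$lambda_min_nonzero)
    }))
  })
  do.call(rbind, rows)
}
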