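# Independent oracles used to cross-check the package's computations.
# These deliberately re-derive everything from first principles and share no
# code path with the implementation under test.

# Exact matrix rank over the prime field GF(p).  Boundary matrices have
# entries in {-1, 0, 1}; their rank over the rationals equals the rank over
# a large prime field (torsion at p = 46337 does not occur in these tiny
# complexes).  All arithmetic stays below 2^53, exact in doubles.
rank_modp <- function(M, p = 46337) {
  if (length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- matrix(as.numeric(M) %% p, nrow(M), ncol(M))
  powmod <- function(a, e) {
    r <- 1; b <- a %% p
    while (e > 0) {
      if (e %% 2 == 1) r <- (r * b) %% p
      b <- (b * b) %% p
      e <- e %/% 2
    }
    r
  }
  r <- 0L
  row <- 1L
  for (col in seq_len(ncol(M))) {
    if (row > nrow(M)) break
    piv <- which(M[row:nrow(M), col] != 0)
    if (!length(piv)) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    M[row, ] <- (M[row, ] * powmod(M[row, col], p - 2)) %% p
    rest <- setdiff(seq_len(nrow(M)), row)
    fac <- M[rest, col]
    nz <- rest[fac != 0]
    if (length(nz))
      M[nz, ] <- (M[nz, , drop = FALSE] -
                    outer(M[nz, col], M[row, ])) %% p
    r <- r + 1L
    row <- row + 1L
  }
  r
}

# Boundary matrix of order q at filtration value t, rebuilt directly from
# the simplex list with the (-1)^i face-sign rule.
oracle_boundary <- function(f, t, q) {
  cols <- which(f$dim == q & f$birth <= t)
  if (q == 0L) return(matrix(0, nrow = 0L, ncol = length(cols)))
  rows <- which(f$dim == q - 1L & f$birth <= t)
  rkey <- vapply(f$verts[rows], paste, "", collapse = ",")
  B <- matrix(0, length(rows), length(cols))
  for (k in seq_along(cols)) {
    v <- f$verts[[cols[k]]]
    for (i in seq_along(v)) {
      ri <- match(paste(v[-i], collapse = ","), rkey)
      B[ri, k] <- (-1)^(i - 1)
    }
  }
  attr(B, "col_birth") <- f$birth[cols]
  attr(B, "row_birth") <- f$birth[rows]
  B
}

# Persistent Betti number by the rank formula:
#   beta_q^{t,p} = dim ker d_q^t - dim( B_q(K_{t+p}) meet C_q(K_t) )
# with the intersection dimension rank(D) - rank(D restricted to the rows
# outside K_t), D the (q+1)-boundary of K_{t+p}.
oracle_persistent_betti <- function(f, t, t_plus_p, q) {
  nq <- sum(f$dim == q & f$birth <= t)
  if (nq == 0L) return(0L)
  Bq <- oracle_boundary(f, t, q)
  zq <- nq - rank_modp(Bq)
  if (q + 1L > max(f$dim)) return(zq)
  D <- oracle_boundary(f, t_plus_p, q + 1L)
  if (ncol(D) == 0L) return(zq)
  inside <- attr(D, "row_birth") <= t
  rD <- rank_modp(D)
  rOut <- rank_modp(D[!inside, , drop = FALSE])
  zq - (rD - rOut)
}

# Plain R reference RK4 step of the coupled Lorenz flow written in the
# direct matrix form ds/dt = f(s) + eps * C %*% (Gamma %*% s)' -- an
# independent re-implementation of the stepping used in compiled code.
reference_rk4 <- function(C, epsilon, pars, init, h, steps) {
  field <- function(S) {
    out <- cbind(pars[1] * (S[, 2] - S[, 1]),
                 pars[2] * S[, 1] - S[, 2] - S[, 1] * S[, 3],
                 S[, 1] * S[, 2] - pars[3] * S[, 3])
    out + epsilon * (C %*% S)
  }
  S <- init
  for (s in seq_len(steps)) {
    k1 <- field(S)
    k2 <- field(S + h / 2 * k1)
    k3 <- field(S + h / 2 * k2)
    k4 <- field(S + h * k3)
    S <- S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  S
}

# seeded random 3-D cloud for property tests
random_cloud <- function(n, seed, spread = 1) {
  set.seed(seed)
  point_cloud(matrix(runif(3 * n, 0, spread), n, 3))
}
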