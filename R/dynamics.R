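#' Oscillator specification
#'
#' Classical three-variable chaotic flows attached to each network node.
#' Lorenz: `(alpha*(y-x), gamma*x - y - x*z, x*y - beta*z)` with defaults
#' `alpha = 10, gamma = 60, beta = 8/3`.  Rossler:
#' `(-y - z, x + a*y, b + z*(x - c))` with defaults `a = b = 0.1, c = 4`.
#' `model = "linear"` is a validation hook, the pure decay `ds/dt = -s`
#' (known closed-form solution) used for integrator checks.
#'
#' @param model `"lorenz"`, `"rossler"` or `"linear"`.
#' @param alpha,gamma,beta Lorenz parameters (dimensionless).
#' @param a,b,c Rossler parameters (dimensionless).
#' @return object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(model = c("lorenz", "rossler", "linear"),
                            alpha = 10, gamma = 60, beta = 8 / 3,
                            a = 0.1, b = 0.1, c = 4) {
  model <- match.arg(model)
  pars <- switch(model,
    lorenz = c(alpha = alpha, gamma = gamma, beta = beta),
    rossler = c(a = a, b = b, c = c),
    linear = numeric(0))
  if (!all(is.finite(pars))) stop("oscillator parameters must be finite")
  structure(list(model = model, pars = pars), class = "oscillator_spec")
}

model_code <- function(spec) {
  switch(spec$model, lorenz = 0L, rossler = 1L, linear = 2L)
}

#' Single-oscillator vector field
#'
#' @param state numeric 3-vector `(x, y, z)`.
#' @param spec an [oscillator_spec()].
#' @return numeric 3-vector, the time derivative.
#' @export
oscillator_field <- function(state, spec = oscillator_spec()) {
  stopifnot(length(state) == 3L, all(is.finite(state)))
  p <- spec$pars
  switch(spec$model,
    lorenz = c(p[["alpha"]] * (state[2L] - state[1L]),
               p[["gamma"]] * state[1L] - state[2L] - state[1L] * state[3L],
               state[1L] * state[2L] - p[["beta"]] * state[3L]),
    rossler = c(-state[2L] - state[3L],
                state[1L] + p[["a"]] * state[2L],
                p[["b"]] + state[3L] * (state[1L] - p[["c"]])),
    linear = -state)
}

#' Coupled oscillator network
#'
#' Combines an oscillator with a symmetric zero-row-sum coupling matrix `C`
#' (a `connectivity_matrix`, the negated filtered Laplacian from
#' [scale_coupling()], or any matrix satisfying the invariants), a coupling
#' strength `epsilon >= 0` and an inner 3x3 coupling matrix `Gamma`
#' (identity by default: all three state variables coupled alike).  Node `i`
#' evolves as
#' `ds_i/dt = f(s_i) + epsilon * sum_j C_ij * Gamma * s_j`,
#' which for zero-row-sum `C` equals the diffusive form
#' `epsilon * sum_{j != i} C_ij * Gamma * (s_j - s_i)` used internally.
#'
#' @param spec an [oscillator_spec()].
#' @param coupling square symmetric matrix with rows summing to zero.
#' @param epsilon coupling strength, `>= 0`.
#' @param gamma_inner 3x3 inner coupling matrix.
#' @return object of class `coupled_system`.
#' @export
coupled_system <- function(spec, coupling, epsilon = 1,
                           gamma_inner = diag(3)) {
  stopifnot(inherits(spec, "oscillator_spec"))
  C <- unname(as.matrix(coupling))
  n <- nrow(C)
  if (n != ncol(C)) stop("coupling matrix must be square")
  if (max(abs(C - t(C))) > 1e-10 * (1 + max(abs(C))))
    stop("coupling matrix must be symmetric")
  if (max(abs(rowSums(C))) > 1e-9 * (1 + max(abs(C))))
    stop("coupling matrix rows must sum to zero")
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  gamma_inner <- as.matrix(gamma_inner)
  stopifnot(all(dim(gamma_inner) == c(3L, 3L)))
  structure(list(spec = spec, coupling = C, epsilon = epsilon,
                 gamma_inner = gamma_inner, n = n,
                 gamma_identity = isTRUE(all.equal(gamma_inner, diag(3)))),
            class = "coupled_system")
}

#' Coupled vector field for a full network state
#'
#' Reference R evaluation of the network right-hand side (the compiled
#' integrator applies the same diffusive difference form).
#'
#' @param states `N x 3` matrix of node states.
#' @param system a [coupled_system()].
#' @return `N x 3` matrix of time derivatives.
#' @export
coupled_field <- function(states, system) {
  states <- as.matrix(states)
  if (nrow(states) != system$n || ncol(states) != 3L)
    stop("states must be ", system$n, " x 3")
  f <- t(apply(states, 1L, oscillator_field, spec = system$spec))
  if (system$epsilon > 0) {
    C <- system$coupling
    for (i in seq_len(system$n)) {
      acc <- c(0, 0, 0)
      for (j in seq_len(system$n)) {
        if (j == i || C[i, j] == 0) next
        acc <- acc + C[i, j] *
          as.numeric(system$gamma_inner %*% (states[j, ] - states[i, ]))
      }
      f[i, ] <- f[i, ] + system$epsilon * acc
    }
  }
  f
}

scheme_code <- function(scheme) {
  switch(match.arg(scheme, c("rk4", "rk2", "euler")),
         euler = 0L, rk2 = 1L, rk4 = 2L)
}

new_trajectory <- function(states, h, scheme, record_every, seed = NULL) {
  nrec <- dim(states)[1L]
  structure(list(times = (seq_len(nrec) - 1L) * h * record_every,
                 states = states, h = h, scheme = scheme,
                 record_every = record_every, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("Trajectory: %d nodes, %d frames (h=%g, %s, every %d steps)\n",
              d[2L], d[1L], x$h, x$scheme, x$record_every))
  invisible(x)
}

#' Integrate a coupled chaotic system
#'
#' Explicit time stepping (forward Euler, midpoint RK2, or classical RK4) of
#' the coupled field.  A divergence guard aborts with the offending step
#' index when any state magnitude exceeds `divergence_bound`.
#'
#' @param system a [coupled_system()].
#' @param initial `N x 3` matrix of initial states.
#' @param h step size, `> 0` (the study default is `1e-3`).
#' @param steps number of steps, `>= 1`.
#' @param scheme `"rk4"` (default), `"rk2"` or `"euler"`.
#' @param record_every keep every m-th frame (all steps are computed).
#' @param divergence_bound abort threshold on `max |state|`.
#' @return object of class `trajectory` with `times` and a
#'   `frames x N x 3` state array.
#' @export
integrate_system <- function(system, initial, h = 1e-3, steps,
                             scheme = "rk4", record_every = 1L,
                             divergence_bound = 1e6) {
  stopifnot(inherits(system, "coupled_system"))
  initial <- as.matrix(initial)
  if (nrow(initial) != system$n || ncol(initial) != 3L)
    stop("initial state must be ", system$n, " x 3")
  if (!is.finite(h) || h <= 0) stop("h must be > 0")
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  ed <- coupling_edges(system$coupling)
  init <- as.numeric(t(initial))  # (node*3 + comp) layout, R = 1
  raw <- cpp_integrate(model_code(system$spec), system$spec$pars,
                       ed$i, ed$j, ed$w, system$epsilon,
                       as.numeric(system$gamma_inner),
                       system$gamma_identity, init, system$n, 1L,
                       h, steps, scheme_code(scheme),
                       as.integer(record_every), 0L, divergence_bound)
  nrec <- attr(raw, "nrec")
  states <- aperm(array(raw, dim = c(3L, system$n, nrec)), c(3L, 2L, 1L))
  new_trajectory(states, h, scheme, as.integer(record_every))
}

#' Perturbative trajectory of one node
#'
#' Starts the network at the origin (an equilibrium of the uncoupled Lorenz
#' and of the linear test flow) with only the chosen node displaced to one,
#' probing how the perturbation spreads through that node's coupling
#' environment.  By default all three state variables of the node are set to
#' 1; `vars = "first"` restricts the kick to the first variable.
#'
#' @inheritParams integrate_system
#' @param node index of the perturbed node.
#' @param init_value initial value given to the perturbed node.
#' @param vars `"all"` (default) or `"first"`.
#' @return a `trajectory` over all nodes.
#' @export
perturbative_trajectory <- function(system, node, h = 1e-3, steps,
                                    scheme = "rk4", init_value = 1,
                                    vars = c("all", "first"),
                                    record_every = 1L,
                                    divergence_bound = 1e6) {
  vars <- match.arg(vars)
  node <- as.integer(node)
  if (node < 1L || node > system$n) stop("node index out of range")
  init <- matrix(0, system$n, 3L)
  if (vars == "all") init[node, ] <- init_value else init[node, 1L] <- init_value
  integrate_system(system, init, h = h, steps = steps, scheme = scheme,
                   record_every = record_every,
                   divergence_bound = divergence_bound)
}

# Batched perturbative integration: run r perturbs node r; only the
# perturbed node's 3 components are recorded per run.  Returns a
# frames x N x 3 array.  Workhorse behind multiscale_features().
perturbative_batch <- function(system, h, steps, scheme = "rk4",
                               init_value = 1, vars = "all",
                               record_every = 1L, divergence_bound = 1e6) {
  n <- system$n
  init <- numeric(n * 3L * n)  # (node*3 + comp)*R + r, R = n runs
  for (r in seq_len(n)) {
    comps <- if (vars == "all") 0:2 else 0L
    idx <- ((r - 1L) * 3L + comps) * n + r
    init[idx] <- init_value
  }
  ed <- coupling_edges(system$coupling)
  raw <- cpp_integrate(model_code(system$spec), system$spec$pars,
                       ed$i, ed$j, ed$w, system$epsilon,
                       as.numeric(system$gamma_inner),
                       system$gamma_identity, init, n, n,
                       h, as.integer(steps), scheme_code(scheme),
                       as.integer(record_every), 1L, divergence_bound)
  nrec <- attr(raw, "nrec")
  aperm(array(raw, dim = c(3L, n, nrec)), c(3L, 2L, 1L))
}

#' Synchronization error time series
#'
#' Mean over node pairs of the Euclidean distance between node states,
#' evaluated at every recorded frame.  With `nodes` the mean runs over pairs
#' inside that subset; with both `nodes` and `against` it runs over the
#' cross pairs, which diagnoses partial synchronization (a subset may
#' synchronize internally while staying apart from the rest).
#'
#' @param traj a `trajectory`.
#' @param nodes optional node subset.
#' @param against optional second subset (cross-set error).
#' @return numeric vector, one value per recorded frame.
#' @export
sync_error <- function(traj, nodes = NULL, against = NULL) {
  st <- traj$states
  n <- dim(st)[2L]
  if (is.null(nodes) && n < 2L) stop("sync error needs at least 2 nodes")
  apply(st, 1L, function(frame) {
    if (is.null(against)) {
      sub <- if (is.null(nodes)) frame else frame[nodes, , drop = FALSE]
      mean(dist(sub))
    } else {
      a <- frame[nodes, , drop = FALSE]
      b <- frame[against, , drop = FALSE]
      sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      mean(sqrt(pmax(sq, 0)))
    }
  })
}

#' Seeded random initial conditions
#'
#' Uniform draws from `[-1, 1]^3` per node; the seed is recorded so runs are
#' reproducible.
#'
#' @param n number of nodes.
#' @param seed integer seed (mandatory).
#' @return `n x 3` matrix with attribute `seed`.
#' @export
random_initial_state <- function(n, seed) {
  if (missing(seed)) stop("seed is mandatory")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  structure(matrix(runif(n * 3L, -1, 1), n, 3L), seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
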