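test_that("oscillator fields match their defining equations", {
  lor <- oscillator_spec("lorenz")
  expect_equal(oscillator_field(c(0, 0, 0), lor), c(0, 0, 0))
  expect_equal(oscillator_field(c(1, 1, 0), lor)[1], 0)
  expect_equal(oscillator_field(c(1, 2, 3), lor),
               c(10 * (2 - 1), 60 * 1 - 2 - 1 * 3, 1 * 2 - 8 / 3 * 3))
  ros <- oscillator_spec("rossler")
  expect_equal(oscillator_field(c(0, 0, 0), ros), c(0, 0, 0.1))
  expect_equal(oscillator_field(c(1, 2, 3), ros),
               c(-2 - 3, 1 + 0.1 * 2, 0.1 + 3 * (1 - 4)))
})

test_that("coupled field equals the direct matrix form", {
  # N = 2 antisymmetric coupling: node 1 feels eps * (s2 - s1)
  C <- matrix(c(-1, 1, 1, -1), 2, 2)
  sys <- coupled_system(oscillator_spec("lorenz"), C, epsilon = 0.7)
  S <- rbind(c(1, 2, 3), c(-1, 0.5, 2))
  f <- coupled_field(S, sys)
  expect_equal(f[1, ], oscillator_field(S[1, ], sys$spec) +
                 0.7 * (S[2, ] - S[1, ]))

  # identical rows: coupling vanishes for any zero-row-sum matrix
  set.seed(3)
  W <- matrix(runif(25), 5, 5); W <- (W + t(W)) / 2
  diag(W) <- 0; diag(W) <- -rowSums(W)
  sysW <- coupled_system(oscillator_spec("lorenz"), W, epsilon = 2)
  Sm <- matrix(rep(c(0.4, -1, 2), each = 5), 5, 3)
  fm <- coupled_field(Sm, sysW)
  expect_equal(fm, t(replicate(5, oscillator_field(c(0.4, -1, 2),
                                                   sysW$spec))))

  # eps = 0 decouples
  sys0 <- coupled_system(oscillator_spec("lorenz"), W, epsilon = 0)
  f0 <- coupled_field(S0 <- matrix(rnorm(15), 5, 3), sys0)
  expect_equal(f0, t(apply(S0, 1, oscillator_field, spec = sys0$spec)))

  # direct C %*% S form agrees (general states)
  fW <- coupled_field(S0, sysW)
  expect_equal(fW, t(apply(S0, 1, oscillator_field, spec = sysW$spec)) +
                 2 * (W %*% S0), tolerance = 1e-12)
})

test_that("RK4 on the linear test system reproduces the textbook step", {
  sys <- coupled_system(oscillator_spec("linear"), matrix(0, 1, 1),
                        epsilon = 0)
  tr <- integrate_system(sys, matrix(1, 1, 3), h = 0.1, steps = 1,
                         scheme = "rk4")
  expect_equal(tr$states[2, 1, 1], 0.9048375)  # RK4 step for ds/dt = -s
  expect_equal(tr$states[2, 1, 1], exp(-0.1), tolerance = 1e-6)
  # euler and midpoint give their characteristic one-step values
  te <- integrate_system(sys, matrix(1, 1, 3), h = 0.1, steps = 1,
                         scheme = "euler")
  expect_equal(te$states[2, 1, 1], 0.9)
  t2 <- integrate_system(sys, matrix(1, 1, 3), h = 0.1, steps = 1,
                         scheme = "rk2")
  expect_equal(t2$states[2, 1, 1], 1 - 0.1 + 0.1^2 / 2)
})

test_that("compiled integrator matches an independent R reference", {
  set.seed(8)
  n <- 6
  W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2
  diag(W) <- 0; diag(W) <- -rowSums(W)
  sys <- coupled_system(oscillator_spec("lorenz"), W, epsilon = 0.9)
  init <- matrix(runif(n * 3, -1, 1), n, 3)
  tr <- integrate_system(sys, init, h = 1e-3, steps = 500,
                         record_every = 500)
  ref <- reference_rk4(W, 0.9, c(10, 60, 8 / 3), init, 1e-3, 500)
  expect_equal(tr$states[2, , ], unname(ref), tolerance = 1e-9)
})

test_that("perturbative runs respect equilibrium and permutation symmetry", {
  # eps = 0: others stay at the origin equilibrium exactly
  Z <- matrix(0, 4, 4)
  sys0 <- coupled_system(oscillator_spec("lorenz"), Z, epsilon = 0)
  tr <- perturbative_trajectory(sys0, 2, steps = 200)
  others <- tr$states[, -2, ]
  expect_true(all(others == 0))
  single <- integrate_system(coupled_system(oscillator_spec("lorenz"),
                                            matrix(0, 1, 1), 0),
                             matrix(1, 1, 3), steps = 200)
  expect_equal(tr$states[, 2, ], single$states[, 1, ])

  # symmetric two-node coupling: perturbing node 1 vs node 2 mirrors
  C <- matrix(c(-1, 1, 1, -1), 2, 2)
  sysC <- coupled_system(oscillator_spec("lorenz"), C, epsilon = 0.5)
  t1 <- perturbative_trajectory(sysC, 1, steps = 300)
  t2 <- perturbative_trajectory(sysC, 2, steps = 300)
  expect_equal(t1$states[, 1, ], t2$states[, 2, ])
  expect_equal(t1$states[, 2, ], t2$states[, 1, ])

  # batched recording agrees with one-at-a-time runs
  arr <- chaoslearn:::perturbative_batch(sysC, h = 1e-3, steps = 300)
  expect_equal(arr[, 1, ], t1$states[, 1, ], tolerance = 1e-12)
  expect_equal(arr[, 2, ], t2$states[, 2, ], tolerance = 1e-12)
})

test_that("divergence is reported with its step index", {
  sys <- coupled_system(oscillator_spec("lorenz"), matrix(0, 1, 1), 0)
  expect_error(integrate_system(sys, matrix(c(1, 1, 1), 1, 3), h = 0.5,
                                steps = 100),
               "diverged at step")
})

test_that("sync error measures pairwise state spread", {
  # constant trajectory 5 apart
  st <- array(0, dim = c(3, 2, 3))
  st[, 2, 1] <- 5
  tr <- structure(list(times = 0:2, states = st, h = 1, scheme = "rk4",
                       record_every = 1), class = "trajectory")
  expect_equal(sync_error(tr), rep(5, 3))
  expect_equal(sync_error(tr, nodes = 1:2), rep(5, 3))
  expect_equal(sync_error(tr, nodes = 1, against = 2), rep(5, 3))

  # identical rows for all t -> exactly zero
  st2 <- array(rnorm(3), dim = c(1, 1, 3))[rep(1, 4), rep(1, 6), ,
                                           drop = FALSE]
  tr2 <- structure(list(times = 0:3, states = st2, h = 1, scheme = "rk4",
                        record_every = 1), class = "trajectory")
  expect_equal(sync_error(tr2), rep(0, 4))
})
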