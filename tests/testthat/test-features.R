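make_traj <- function(series) {
  # wrap a T x 3 matrix as a single-node trajectory
  st <- array(series, dim = c(nrow(series), 1, 3))
  structure(list(times = seq_len(nrow(series)) - 1, states = st, h = 1,
                 scheme = "rk4", record_every = 1), class = "trajectory")
}

test_that("trajectory statistics match hand values and a two-pass oracle", {
  const <- make_traj(matrix(2.5, 10, 3))
  s <- trajectory_statistics(const, 1, transient_fraction = 0)
  expect_equal(unname(s[c("x_mean", "x_sd", "x_min", "x_max", "x_median",
                          "x_rms")]),
               c(2.5, 0, 2.5, 2.5, 2.5, 2.5))
  expect_equal(unname(s["x_skewness"]), 0)

  tri <- make_traj(matrix(c(-1, 0, 1), 3, 3))
  s2 <- trajectory_statistics(tri, 1, transient_fraction = 0)
  expect_equal(unname(s2["x_mean"]), 0)
  expect_equal(unname(s2["x_sd"]), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(s2[c("x_min", "x_max")]), c(-1, 1))

  # every statistic equals an independent recomputation on a Lorenz run
  sys <- coupled_system(oscillator_spec("lorenz"), matrix(0, 1, 1), 0)
  tr <- integrate_system(sys, matrix(c(1, 1, 1), 1, 3), steps = 500)
  got <- trajectory_statistics(tr, 1, transient_fraction = 0.1)
  x <- tr$states[51:501, 1, 1]
  m <- mean(x); mom <- function(k) mean((x - m)^k)
  expect_equal(unname(got["x_mean"]), m, tolerance = 1e-10)
  expect_equal(unname(got["x_sd"]), sqrt(mom(2)), tolerance = 1e-10)
  expect_equal(unname(got["x_skewness"]), mom(3) / mom(2)^1.5,
               tolerance = 1e-10)
  expect_equal(unname(got["x_kurtosis"]), mom(4) / mom(2)^2,
               tolerance = 1e-10)
  expect_equal(unname(got["x_rms"]), sqrt(mean(x^2)), tolerance = 1e-10)
  expect_error(trajectory_statistics(tr, 1, transient_fraction = 1), "\\[0, 1\\)")
})

test_that("multiscale features are deterministic and permutation-equivariant", {
  cl <- random_cloud(10, seed = 44)
  a <- build_connectivity(pairwise_distances(cl), kernel_spec(sigma = 0.6))
  fam <- laplacian_filtration(a, 4)
  f1 <- multiscale_features(fam, oscillator_spec("lorenz"), epsilon = 1,
                            steps = 300)
  f2 <- multiscale_features(fam, oscillator_spec("lorenz"), epsilon = 1,
                            steps = 300)
  expect_identical(unclass(f1)[, ], unclass(f2)[, ])  # bitwise reproducible
  expect_equal(dim(f1), c(10, 4 * 3 * 8))

  # permuting node ids permutes feature rows identically
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  ap <- build_connectivity(pairwise_distances(cl$coords[perm, ]),
                           kernel_spec(sigma = 0.6))
  famp <- laplacian_filtration(ap, 4)
  fp <- multiscale_features(famp, oscillator_spec("lorenz"), epsilon = 1,
                            steps = 300)
  expect_equal(unclass(fp)[, ], unclass(f1)[perm, ], tolerance = 1e-12)

  # shared protocol requires a seed and then reproduces bitwise
  expect_error(multiscale_features(fam, protocol = "shared", steps = 100),
               "seed")
  g1 <- multiscale_features(fam, protocol = "shared", steps = 100, seed = 9)
  g2 <- multiscale_features(fam, protocol = "shared", steps = 100, seed = 9)
  expect_identical(unclass(g1)[, ], unclass(g2)[, ])
})

test_that("synchronized scales compress between-node feature variance", {
  # 16-gon: dense scale synchronizes, empty scale stays chaotic
  pc <- polygon_cloud(16)
  a <- build_connectivity(pairwise_distances(pc), kernel_spec())
  fam <- laplacian_filtration(a, 10)
  f <- multiscale_features(fam, oscillator_spec("lorenz"), epsilon = 1.1,
                           protocol = "shared", steps = 2000, seed = 17)
  v_dense <- mean(apply(f[, grep("^k1_", colnames(f))], 2, var))
  v_empty <- mean(apply(f[, grep("^k10_", colnames(f))], 2, var))
  expect_lt(v_dense, v_empty)
})

test_that("pearson correlation obeys closed forms and affine invariance", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cc(x, 3 * x + 2), 1)
  expect_equal(pearson_cc(x, -x), -1)
  expect_equal(pearson_cc(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_cc(x, rep(1, 4)), "constant")
  set.seed(2)
  for (i in 1:100) {
    u <- rnorm(20); v <- rnorm(20)
    r <- pearson_cc(u, v)
    aa <- runif(1, 0.1, 5); bb <- rnorm(1)
    expect_equal(pearson_cc(aa * u + bb, v), r, tolerance = 1e-12)
  }
})

test_that("B-factor regression recovers exact and null relationships", {
  set.seed(10)
  X <- matrix(rnorm(200 * 5), 200, 5)
  b <- 3 * X[, 2] + 1
  fit <- fit_bfactor_regression(X, b)
  expect_equal(fit$pcc, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$predictions - b)), 1e-8)
  expect_equal(fit$method, "ols")

  # independent b: PCC stays near zero at N = 500
  set.seed(11)
  Xn <- matrix(rnorm(500 * 5), 500, 5)
  bn <- rnorm(500)
  expect_lt(abs(fit_bfactor_regression(Xn, bn)$pcc), 0.2)

  # duplicated column triggers the recorded ridge fallback
  Xd <- cbind(X, X[, 1])
  fd <- fit_bfactor_regression(Xd, b)
  expect_equal(fd$method, "ridge")
  expect_gt(fd$ridge, 0)
  expect_error(fit_bfactor_regression(matrix(rnorm(40), 10, 4), rnorm(10),
                                      reduce = NULL), NA)
  expect_error(fit_bfactor_regression(matrix(rnorm(40), 4, 10), rnorm(4)),
               "observations")
})

test_that("balanced accuracy averages per-class recalls", {
  expect_equal(balanced_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # 90/10 majority vote: (1 + 0) / 2
  truth <- rep(c("a", "b"), c(90, 10))
  expect_equal(balanced_accuracy(truth, rep("a", 100)), 0.5)
  # recalls (1, 0.5, 0) -> 0.5
  truth3 <- rep(c("a", "b", "c"), each = 2)
  pred3 <- c("a", "a", "b", "c", "a", "b")
  expect_equal(balanced_accuracy(truth3, pred3), 0.5)
  expect_error(balanced_accuracy(factor(c("a", "a"), levels = c("a", "b")),
                                 c("a", "a")), "absent")
  # equals plain accuracy on balanced labels
  set.seed(4)
  for (i in 1:20) {
    tr <- rep(c("x", "y", "z"), each = 10)
    pr <- sample(c("x", "y", "z"), 30, replace = TRUE)
    expect_equal(balanced_accuracy(tr, pr),
                 mean(tapply(pr == tr, tr, mean)))
  }
})

test_that("cross-validation is stratified, seeded and adapter-driven", {
  set.seed(12)
  x <- rbind(matrix(rnorm(40 * 2), 40, 2),
             matrix(rnorm(40 * 2, mean = 8), 40, 2))
  y <- rep(c("a", "b"), each = 40)
  cv <- cross_validate(x, y, folds = 5, seeds = 1:2,
                       classifier = classifier_knn(3))
  expect_equal(cv$summary$mean_ba, 1)
  expect_equal(sum(cv$confusion), 2 * 80)

  # same seed -> identical folds; different seed -> different
  cv2 <- cross_validate(x, y, folds = 5, seeds = 1:2,
                        classifier = classifier_knn(3))
  expect_identical(cv$results, cv2$results)

  # permutation null on 4 balanced classes sits at chance
  set.seed(13)
  xr <- matrix(rnorm(120 * 3), 120, 3)
  yr <- sample(rep(letters[1:4], each = 30))
  cvn <- cross_validate(xr, yr, folds = 5, seeds = 1:10,
                        classifier = classifier_knn(5))
  expect_lt(abs(cvn$summary$mean_ba - 0.25), 0.05)

  expect_error(cross_validate(x[1:6, ], c("a", "a", "a", "a", "a", "b"),
                              folds = 3), "fewer")
})

test_that("residue and similarity scores normalize into the unit square", {
  # two collapsed classes: similarity 1 everywhere
  x <- rbind(matrix(0, 4, 2), matrix(1, 4, 2))
  y <- rep(c("a", "b"), each = 4)
  rs <- rs_scores(x, y)
  expect_equal(rs$similarity, rep(1, 8))
  expect_equal(rs$residue, rep(1, 8))  # all inter-class means equal the max

  # all identical: residue 0
  rs0 <- rs_scores(matrix(1, 6, 2), rep(c("a", "b"), 3))
  expect_equal(rs0$residue, rep(0, 6))
  expect_equal(rs0$similarity, rep(1, 6))

  # hand-evaluated 2-class planar example with unit separation
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
               c(5, 0), c(6, 0), c(5, 1), c(6, 1))
  lab <- rep(c("l", "r"), each = 4)
  rs2 <- rs_scores(pts, lab)
  dmat <- as.matrix(dist(pts))
  dmax <- max(dmat)
  expect_equal(rs2$similarity[1], mean(1 - dmat[1, 2:4] / dmax))
  expect_equal(rs2$residue[1],
               mean(dmat[1, 5:8]) /
                 max(sapply(1:8, function(i)
                   mean(dmat[i, lab != lab[i]]))))
  expect_true(all(rs2$residue >= 0 & rs2$residue <= 1))
  expect_true(all(rs2$similarity >= 0 & rs2$similarity <= 1))

  # property: bounds hold on random inputs
  set.seed(14)
  for (i in 1:10) {
    xr <- matrix(rnorm(30), 10, 3)
    yr <- rep(c("a", "b"), 5)
    r <- rs_scores(xr, yr)
    expect_true(all(r$residue >= 0 & r$residue <= 1))
    expect_true(all(r$similarity >= 0 & r$similarity <= 1))
  }
  expect_error(rs_scores(matrix(rnorm(6), 3), c("a", "a", "b")),
               "singleton")
})
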