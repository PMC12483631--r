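# a small handcrafted PDB fixture writer
write_mini_pdb <- function(path, altloc = FALSE, chains = "A",
                           res_per_chain = 2) {
  lines <- character(0)
  serial <- 1
  for (ch in chains) {
    for (r in seq_len(res_per_chain)) {
      x <- 3.8 * r + 10 * match(ch, chains)
      if (altloc && r == 1 && ch == chains[1]) {
        lines <- c(lines, sprintf(
          "ATOM  %5d  CA ASER %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, ch, r, x, 1.0, 2.0, 0.60, 11.11))
        serial <- serial + 1
        lines <- c(lines, sprintf(
          "ATOM  %5d  CA BSER %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, ch, r, x + 0.5, 1.0, 2.0, 0.40, 99.99))
        serial <- serial + 1
      } else {
        lines <- c(lines, sprintf(
          "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, ch, r, x, 1.5 * r, 2.0, 1.00, 10 * r))
        serial <- serial + 1
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("PDB C-alpha reading honours altlocs, chains and B-factors", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  ch <- read_pdb_calpha(p)
  expect_equal(length(ch$resid), 2)
  expect_equal(ch$coords[1, ], c(3.8 + 10, 1.5, 2.0))
  expect_equal(ch$bfactors, c(10, 20))

  # altloc A (occupancy 0.6) wins over B (0.4)
  pa <- write_mini_pdb(tempfile(fileext = ".pdb"), altloc = TRUE)
  cha <- read_pdb_calpha(pa)
  expect_equal(length(cha$resid), 2)
  expect_equal(cha$bfactors[1], 11.11)

  # chain filter keeps only the requested chain
  p3 <- write_mini_pdb(tempfile(fileext = ".pdb"),
                       chains = c("A", "B", "C"), res_per_chain = 3)
  all3 <- read_pdb_calpha(p3)
  expect_equal(length(all3$resid), 9)
  onlyb <- read_pdb_calpha(p3, chain = "B")
  expect_equal(length(onlyb$resid), 3)
  expect_true(all(onlyb$chain == "B"))

  empty <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing", "END"), empty)
  expect_error(read_pdb_calpha(empty))
})

test_that("B-factor pipeline is reproducible and rejects degenerate targets", {
  pr <- synthetic_protein(40, noise_sd = 0.05, seed = 20)
  cfg <- pipeline_config(p = 4L, steps = 300L, seed = 2)
  rep1 <- run_bfactor(pr, cfg)
  rep2 <- run_bfactor(pr, cfg)
  expect_identical(rep1$fit$predictions, rep2$fit$predictions)  # bitwise
  expect_equal(nrow(rep1$table), 40)
  expect_true(is.finite(rep1$pcc))

  # constant B-factors surface the undefined-correlation error cleanly
  pr$bfactors <- rep(1, 40)
  expect_error(run_bfactor(pr, cfg), "constant")

  short <- synthetic_protein(20, 0.05, seed = 3)
  short$coords <- short$coords[1:10, ]
  short$bfactors <- short$bfactors[1:10]
  expect_error(run_bfactor(short, cfg), "20 residues")
})

test_that("duplicating residues leaves the fitted PCC unchanged", {
  pr <- synthetic_protein(40, noise_sd = 0.05, seed = 21)
  cfg <- pipeline_config(p = 4L, steps = 300L, reduce = 10L, seed = 2)
  base <- run_bfactor(pr, cfg)$pcc
  # exact duplication of every residue (coordinates and targets)
  dup <- pr
  dup$resid <- c(pr$resid, pr$resid)
  dup$chain <- c(pr$chain, pr$chain)
  dup$coords <- rbind(pr$coords, pr$coords)
  dup$bfactors <- c(pr$bfactors, pr$bfactors)
  dup2 <- run_bfactor(dup, cfg)$pcc
  expect_equal(dup2, base, tolerance = 2e-2)
})

test_that("classification pipeline handles the signal modality end to end", {
  ds <- synthetic_signals(12, classes = 3, T = 1500, within_r = 0.8,
                          across_r = 0.1, seed = 30)
  cfg <- pipeline_config(p = 6L, steps = 600L, folds = 3L, cv_seeds = 1:2,
                         classifier = classifier_knn(3), seed = 5)
  rep <- run_classification(ds, cfg)
  expect_gt(rep$cv$summary$mean_ba, 0.9)
  # reproducible bitwise under the same master seed
  rep2 <- run_classification(ds, cfg)
  expect_identical(rep$cv$results, rep2$cv$results)
  expect_identical(unclass(rep$features)[, ], unclass(rep2$features)[, ])
})

test_that("scrna preprocessing drops exactly the flat genes", {
  ds <- synthetic_expression(20, types = 2, genes = 50,
                             marker_fraction = 0.1, effect_size = 3,
                             seed = 31)
  ds$x[, 7] <- 5L   # constant gene: zero variance after log transform
  ds$x[, 19] <- 0L
  cfg <- pipeline_config(p = 3L, steps = 200L, folds = 2L, cv_seeds = 1,
                         classifier = classifier_knn(3), seed = 6)
  rep <- run_classification(ds, cfg)
  lx <- log1p(ds$x)
  expect_equal(rep$provenance$dropped_genes,
               sum(apply(lx, 2, var) < 1e-6))
  expect_gte(rep$provenance$dropped_genes, 2)
})

test_that("image modality reduces to 3 dimensions before the kernel", {
  set.seed(32)
  x <- rbind(matrix(rnorm(15 * 40), 15, 40),
             matrix(rnorm(15 * 40, mean = 2), 15, 40))
  ds <- structure(list(x = x, labels = factor(rep(c("a", "b"), each = 15)),
                       modality = "image"), class = "labeled_dataset")
  seen <- NULL
  cfg <- pipeline_config(p = 3L, steps = 1500L, folds = 3L, cv_seeds = 1,
                         classifier = classifier_knn(3), seed = 7,
                         reducer = function(x, ndim) {
                           seen <<- ndim
                           pca_reducer(x, ndim)
                         })
  rep <- run_classification(ds, cfg)
  expect_equal(seen, 3L)
  expect_gt(rep$cv$summary$mean_ba, 0.9)
})

test_that("feature tables round-trip through their text export", {
  cl <- random_cloud(6, seed = 50)
  fam <- laplacian_filtration(
    build_connectivity(pairwise_distances(cl), kernel_spec(sigma = 0.6)), 3)
  f <- multiscale_features(fam, steps = 200, epsilon = 1)
  path <- tempfile(fileext = ".tsv")
  write_features(f, path)
  back <- as.matrix(read.table(path, header = TRUE, sep = "\t"))
  expect_equal(unname(back), unname(unclass(f)[, ]), tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".provenance")))
})
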