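# Seed-deterministic generators that reproduce the geometric and statistical
# structure of the method's input classes at desk scale, so every pipeline is
# testable without external downloads.  Each generator records its parameters
# in a `generator` attribute.

with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

generator_spec <- function(.generator, ...) {
  list(generator = .generator, params = list(...))
}

#' Regular polygon point cloud
#'
#' `n` equally spaced points on a circle of the given circumradius in the
#' `z = 0` plane (the 16-node regular hexadecagon of the synchronization
#' demonstration is `polygon_cloud(16)`).  Nearest-neighbour distances all
#' equal `2 * r * sin(pi / n)`.
#'
#' @param n number of nodes, `>= 3`.
#' @param circumradius circle radius.
#' @return a [point_cloud()].
#' @export
polygon_cloud <- function(n = 16L, circumradius = 1) {
  if (n < 3L) stop("a polygon needs at least 3 nodes")
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  pc <- point_cloud(cbind(circumradius * cos(theta),
                          circumradius * sin(theta), 0))
  attr(pc, "generator") <- generator_spec("polygon_cloud", n = n,
                                          circumradius = circumradius)
  pc
}

# boustrophedon path through an a x b x c grid: consecutive nodes always at
# unit distance, the whole block compact (the "folded" conformation)
snake_grid <- function(n) {
  a <- max(2L, round(n^(1 / 3)))
  b <- max(2L, ceiling(sqrt(n / a)))
  cc <- ceiling(n / (a * b))
  coords <- matrix(0, a * b * cc, 3L)
  k <- 1L
  for (z in seq_len(cc)) {
    ys <- if (z %% 2L == 1L) seq_len(b) else rev(seq_len(b))
    for (y in ys) {
      xs <- if ((y + z) %% 2L == 0L) seq_len(a) else rev(seq_len(a))
      for (x in xs) {
        coords[k, ] <- c(x, y, z)
        k <- k + 1L
      }
    }
  }
  coords[seq_len(n), , drop = FALSE]
}

#' Folded / partially folded / unfolded chain cloud
#'
#' A chain of `n` nodes whose leading `folded_fraction` runs as a compact
#' globule (grid-snake of straight segments and turns, consecutive spacing
#' about 1: dense contacts) and whose remainder extends as a straight tail
#' with spacing about 3 (no contacts within typical kernel ranges).  Small
#' seeded Gaussian jitter (sd 0.05) breaks exact degeneracies.  With
#' `n = 120, folded_fraction = 2/3` this reproduces the 80 folded / 40
#' unfolded partial conformation; fractions 1 and 0 give the fully folded
#' and fully unfolded analogues.
#'
#' @param n chain length, `>= 10`.
#' @param folded_fraction fraction of nodes in the folded block, in
#'   `[0, 1]`.
#' @param seed jitter seed (mandatory).
#' @param jitter_sd Gaussian jitter standard deviation.
#' @return a [point_cloud()] with an extra element `labels`
#'   (`"folded"`/`"unfolded"` per node).
#' @export
chain_cloud <- function(n = 120L, folded_fraction = 2 / 3, seed,
                        jitter_sd = 0.05) {
  if (n < 10L) stop("n must be >= 10")
  if (folded_fraction < 0 || folded_fraction > 1)
    stop("folded_fraction must be in [0, 1]")
  n_f <- round(n * folded_fraction)
  with_seed(seed, {
    coords <- matrix(0, n, 3L)
    if (n_f > 0L) coords[seq_len(n_f), ] <- snake_grid(n_f)
    if (n_f < n) {
      start <- if (n_f > 0L) coords[n_f, ] else c(0, 0, 0)
      dirv <- c(1, 1, 1) / sqrt(3)
      tail_idx <- seq.int(n_f + 1L, n)
      for (m in seq_along(tail_idx))
        coords[tail_idx[m], ] <- start + (2 + 3 * m) * dirv
    }
    coords <- coords + matrix(rnorm(3L * n, sd = jitter_sd), n, 3L)
    pc <- point_cloud(coords)
    pc$labels <- rep(c("folded", "unfolded"), c(n_f, n - n_f))
    attr(pc, "generator") <- generator_spec("chain_cloud", n = n,
                                            folded_fraction = folded_fraction,
                                            seed = seed,
                                            jitter_sd = jitter_sd)
    pc
  })
}

new_labeled_dataset <- function(x, labels, modality, generator = NULL) {
  structure(list(x = x, labels = factor(labels), modality = modality),
            generator = generator, class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset (%s): %d samples x %d dims, %d classes\n",
              x$modality, nrow(x$x), ncol(x$x), nlevels(x$labels)))
  invisible(x)
}

#' Correlated signal bundles
#'
#' Gaussian signals with block correlation structure built from shared
#' latent factors: a global factor contributes `across_r` to every pairwise
#' correlation, a class factor raises within-class correlations to
#' `within_r`.  Requires `0 <= across_r < within_r < 1` (any other
#' combination is not realisable as a positive-semidefinite block model of
#' this form).
#'
#' @param n_per_class signals per class.
#' @param classes number of classes, `>= 2`.
#' @param T samples per signal.
#' @param within_r target within-class correlation.
#' @param across_r target across-class correlation.
#' @param seed mandatory seed.
#' @return a `labeled_dataset` with modality `"eeg"`; `x` is
#'   `(classes * n_per_class) x T` with one signal per row.
#' @export
synthetic_signals <- function(n_per_class, classes = 3L, T = 1000L,
                              within_r = 0.8, across_r = 0.1, seed) {
  if (!(across_r >= 0 && across_r < within_r && within_r < 1))
    stop("need 0 <= across_r < within_r < 1 (block model not PSD otherwise)")
  with_seed(seed, {
    a <- sqrt(across_r)
    b <- sqrt(within_r - across_r)
    cnoise <- sqrt(1 - within_r)
    g <- rnorm(T)
    x <- matrix(0, classes * n_per_class, T)
    labels <- character(classes * n_per_class)
    row <- 1L
    for (cl in seq_len(classes)) {
      fc <- rnorm(T)
      for (i in seq_len(n_per_class)) {
        x[row, ] <- a * g + b * fc + cnoise * rnorm(T)
        labels[row] <- paste0("class", cl)
        row <- row + 1L
      }
    }
    new_labeled_dataset(x, labels, "eeg",
                        generator_spec("synthetic_signals",
                                       n_per_class = n_per_class,
                                       classes = classes, T = T,
                                       within_r = within_r,
                                       across_r = across_r, seed = seed))
  })
}

#' Clustered expression-count matrix
#'
#' Negative-binomial-like counts for `types` cell types: each gene gets a
#' log-normal baseline mean, each type up-regulates its own disjoint block
#' of marker genes (`marker_fraction` of all genes) by `effect_size` fold,
#' and per-cell library sizes vary uniformly over `[0.5, 2]`.
#' `effect_size = 1` is the no-signal null.
#'
#' @param cells_per_type cells per type.
#' @param types number of cell types, `>= 2`.
#' @param genes number of genes.
#' @param marker_fraction fraction of genes marking each type, in `(0, 1)`;
#'   `types * marker_fraction <= 1` so marker blocks stay disjoint.
#' @param effect_size fold change of marker genes, `>= 1`.
#' @param seed mandatory seed.
#' @param dispersion negative-binomial size parameter.
#' @return a `labeled_dataset` with modality `"scrna"`; `x` is a
#'   cells x genes count matrix.
#' @export
synthetic_expression <- function(cells_per_type = 125L, types = 4L,
                                 genes = 200L, marker_fraction = 0.1,
                                 effect_size = 4, seed, dispersion = 2) {
  if (types < 2L) stop("need at least 2 types")
  if (marker_fraction <= 0 || marker_fraction >= 1)
    stop("marker_fraction must be in (0, 1)")
  m <- round(marker_fraction * genes)
  if (types * m > genes) stop("marker blocks exceed the gene count")
  with_seed(seed, {
    base_mu <- exp(rnorm(genes, mean = log(5), sd = 1))
    n_cells <- cells_per_type * types
    counts <- matrix(0L, n_cells, genes)
    labels <- rep(paste0("type", seq_len(types)), each = cells_per_type)
    libsize <- runif(n_cells, 0.5, 2)
    for (t in seq_len(types)) {
      markers <- seq.int((t - 1L) * m + 1L, t * m)
      rows <- which(labels == paste0("type", t))
      mu <- base_mu
      mu[markers] <- mu[markers] * effect_size
      for (i in rows)
        counts[i, ] <- rnbinom(genes, size = dispersion,
                               mu = libsize[i] * mu)
    }
    new_labeled_dataset(counts, labels, "scrna",
                        generator_spec("synthetic_expression",
                                       cells_per_type = cells_per_type,
                                       types = types, genes = genes,
                                       marker_fraction = marker_fraction,
                                       effect_size = effect_size,
                                       seed = seed,
                                       dispersion = dispersion))
  })
}

#' Elastic-chain pseudo-protein with known flexibility profile
#'
#' Generates a compact C-alpha trace (helical segments joined by seeded
#' turns, consecutive spacing 3.8 Angstrom, segments steered back toward the
#' centroid so the fold stays globular), derives a ground-truth flexibility
#' profile as the diagonal of the pseudo-inverse of the cutoff-kernel
#' elastic-network Laplacian of the trace, and emits B-factors as an affine
#' transform of that profile plus Gaussian noise with
#' `sd = noise_sd * sd(signal)`.  `noise_sd = 0` makes the B-factors a
#' perfect affine image of the truth.
#'
#' @param n_residues chain length, `>= 20`.
#' @param noise_sd relative noise level (0.05 = 5 percent).
#' @param seed mandatory seed.
#' @param enm_cutoff elastic-network cutoff distance (Angstrom).
#' @return object of class `protein_chain` (see [read_pdb_calpha()]) with
#'   extra element `flexibility` (the ground truth).
#' @export
synthetic_protein <- function(n_residues = 100L, noise_sd = 0.05, seed,
                              enm_cutoff = 8) {
  if (n_residues < 20L) stop("n_residues must be >= 20")
  with_seed(seed, {
    # ideal alpha-helix geometry scaled to 3.8 A Calpha-Calpha spacing
    rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
    seg_len <- 14L
    coords <- matrix(0, n_residues, 3L)
    origin <- c(0, 0, 0); axis <- c(0, 0, 1)
    phase <- 0; base <- origin
    # orthonormal frame perpendicular to the axis
    frame <- function(ax) {
      u <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- u - sum(u * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(ax[2L] * e1[3L] - ax[3L] * e1[2L],
              ax[3L] * e1[1L] - ax[1L] * e1[3L],
              ax[1L] * e1[2L] - ax[2L] * e1[1L])
      cbind(e1, e2)
    }
    fr <- frame(axis)
    k_in_seg <- 0L
    for (i in seq_len(n_residues)) {
      coords[i, ] <- base + k_in_seg * rise * axis +
        radius * (cos(phase) * fr[, 1L] + sin(phase) * fr[, 2L])
      phase <- phase + twist
      k_in_seg <- k_in_seg + 1L
      if (k_in_seg == seg_len && i < n_residues) {
        # turn: new axis drawn at random, biased back toward the centroid
        centroid <- colMeans(coords[seq_len(i), , drop = FALSE])
        pull <- centroid - coords[i, ]
        pn <- sqrt(sum(pull^2))
        dirv <- rnorm(3L) + if (pn > 0) 1.5 * pull / pn else 0
        axis <- dirv / sqrt(sum(dirv^2))
        fr <- frame(axis)
        base <- coords[i, ] + 2.5 * axis
        phase <- runif(1L, 0, 2 * pi)
        k_in_seg <- 0L
      }
    }
    coords <- coords + matrix(rnorm(3L * n_residues, sd = 0.05),
                              n_residues, 3L)
    # elastic-network ground truth: Kirchhoff matrix of the cutoff contact
    # graph; flexibility = diag of its pseudo-inverse
    d <- as.matrix(dist(coords))
    kirch <- -(d <= enm_cutoff & d > 0) * 1
    diag(kirch) <- -rowSums(kirch)
    flex <- diag(MASS::ginv(kirch))
    # affine map onto a strictly positive range so the noiseless profile
    # stays a perfect affine image of the truth
    b <- 5 + 30 * (flex - min(flex)) / (max(flex) - min(flex))
    b <- pmax(b + rnorm(n_residues, sd = noise_sd * sd(b)), 0.01)
    structure(list(resid = seq_len(n_residues),
                   chain = rep("A", n_residues),
                   coords = coords, bfactors = b,
                   source = sprintf("synthetic(seed=%d)", as.integer(seed)),
                   flexibility = flex),
              generator = generator_spec("synthetic_protein",
                                         n_residues = n_residues,
                                         noise_sd = noise_sd, seed = seed,
                                         enm_cutoff = enm_cutoff),
              class = "protein_chain")
  })
}
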