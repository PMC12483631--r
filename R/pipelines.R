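#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end drivers with the study defaults:
#' exponential kernel `kappa = 1, sigma = 3`; `p = 10` filtration scales;
#' Lorenz oscillator `alpha = 10, gamma = 60, beta = 8/3`; coupling
#' `epsilon = 13.6` for the per-residue protein protocol and `epsilon = 1`
#' for the shared-run classification protocol; step `h = 1e-3` with RK4.
#' All values are validated up front and serialized verbatim into every
#' output's provenance.
#'
#' @param kernel a [kernel_spec()].
#' @param p number of filtration scales.
#' @param oscillator an [oscillator_spec()].
#' @param epsilon coupling strength for perturbative (protein) runs.
#' @param epsilon_shared coupling strength for shared (signal/cell/image)
#'   runs.
#' @param h,steps,scheme,record_every integration controls.
#' @param transient_fraction leading fraction of frames discarded.
#' @param stats statistic set.
#' @param folds,cv_seeds cross-validation controls.
#' @param classifier classifier adapter.
#' @param reduce feature count kept by variance ranking before fits
#'   (`NULL` = keep all).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param reducer image-modality dimension reducer,
#'   `f(x, ndim) -> matrix`; default is PCA.
#' @param protocol trajectory protocol override for classification
#'   (`"perturbative"`/`"shared"`); `NULL` applies the per-modality rule
#'   (perturbative for images, shared otherwise).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(kernel = kernel_spec("exponential", sigma = 3,
                                                 kappa = 1L),
                            p = 10L,
                            oscillator = oscillator_spec("lorenz"),
                            epsilon = 13.6, epsilon_shared = 1,
                            h = 1e-3, steps = 2000L, scheme = "rk4",
                            record_every = 1L, transient_fraction = 0.1,
                            stats = default_statistics(),
                            folds = 5L, cv_seeds = 1:10,
                            classifier = classifier_rf(), reduce = 30L,
                            seed = 1L, reducer = pca_reducer,
                            protocol = NULL) {
  stopifnot(inherits(kernel, "kernel_spec"),
            inherits(oscillator, "oscillator_spec"),
            p >= 1L, h > 0, steps >= 1L, folds >= 2L,
            transient_fraction >= 0, transient_fraction < 1,
            epsilon >= 0, epsilon_shared >= 0)
  structure(list(kernel = kernel, p = as.integer(p),
                 oscillator = oscillator, epsilon = epsilon,
                 epsilon_shared = epsilon_shared, h = h,
                 steps = as.integer(steps), scheme = scheme,
                 record_every = as.integer(record_every),
                 transient_fraction = transient_fraction, stats = stats,
                 folds = as.integer(folds), cv_seeds = cv_seeds,
                 classifier = classifier, reduce = reduce,
                 seed = as.integer(seed), reducer = reducer,
                 protocol = protocol),
            class = "pipeline_config")
}

#' PCA reduction to a few components
#'
#' Default image-modality reducer: centred principal components.
#'
#' @param x sample matrix.
#' @param ndim number of components.
#' @return samples x `ndim` score matrix.
#' @export
pca_reducer <- function(x, ndim = 3L) {
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = ndim)
  p$x[, seq_len(ndim), drop = FALSE]
}

#' Read C-alpha records from a PDB file
#'
#' Extracts the C-alpha trace of the first model: coordinates (Angstrom)
#' and experimental B-factors from the temperature-factor column, one
#' residue per C-alpha.  Alternate locations are resolved by highest
#' occupancy, ties by alternate-location label order; insertion codes are
#' preserved in the residue ids.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier filter.
#' @return object of class `protein_chain`: `resid` (residue ids, insertion
#'   codes appended), `chain`, `coords` (N x 3), `bfactors`, `source`.
#' @export
read_pdb_calpha <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) ca <- ca[ca$chain %in% chain, , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms found in ", path)
  ins <- ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert)
  key <- paste(ca$chain, ca$resno, ins, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, unique(key))),
                        function(rows) {
    if (length(rows) == 1L) return(rows)
    occ <- ca$o[rows]
    alt <- as.character(ca$alt[rows])
    rows[order(-occ, alt)][1L]  # highest occupancy, then altloc label
  }), use.names = FALSE)
  keep <- sort(keep)
  ca <- ca[keep, , drop = FALSE]
  ins <- ins[keep]
  coords <- as.matrix(ca[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("malformed coordinates in ", path)
  structure(list(resid = paste0(ca$resno, ins), chain = ca$chain,
                 coords = unname(coords), bfactors = ca$b,
                 source = path),
            class = "protein_chain")
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("Protein chain: %d residues from %s\n", length(x$resid),
              x$source))
  invisible(x)
}

provenance <- function(config, ...) {
  c(list(kernel = unclass(config$kernel), p = config$p,
         model = config$oscillator$model, pars = config$oscillator$pars,
         h = config$h, steps = config$steps, scheme = config$scheme,
         seed = config$seed,
         package_version = as.character(utils::packageVersion("chaoslearn"))),
    list(...))
}

#' Protein B-factor pipeline
#'
#' The per-residue protocol: C-alpha distances, exponential-kernel
#' connectivity, Laplacian filtration into `p` scales, one perturbative
#' Lorenz trajectory per residue and scale, trajectory statistics,
#' variance-reduced per-protein ordinary least squares against the
#' experimental B-factors, and the Pearson correlation of fitted versus
#' experimental values.
#'
#' @param chain a `protein_chain` (>= 20 residues).
#' @param config a [pipeline_config()].
#' @return list of class `bfactor_report`: the `regression_result`, the
#'   `feature_matrix`, a per-residue `table` (residue id, experimental and
#'   predicted B-factor), and `provenance`.
#' @export
run_bfactor <- function(chain, config = pipeline_config()) {
  stopifnot(inherits(chain, "protein_chain"))
  n <- nrow(chain$coords)
  if (n < 20L) stop("need at least 20 residues")
  d <- pairwise_distances(chain$coords)
  a <- build_connectivity(d, config$kernel)
  fam <- laplacian_filtration(a, config$p)
  feats <- multiscale_features(fam, config$oscillator,
                               epsilon = config$epsilon,
                               protocol = "perturbative", h = config$h,
                               steps = config$steps, scheme = config$scheme,
                               record_every = config$record_every,
                               stats = config$stats,
                               transient_fraction =
                                 config$transient_fraction)
  fit <- fit_bfactor_regression(feats, chain$bfactors,
                                reduce = config$reduce)
  structure(list(fit = fit, features = feats,
                 table = data.frame(resid = chain$resid,
                                    experimental = chain$bfactors,
                                    predicted = fit$predictions),
                 pcc = fit$pcc,
                 provenance = provenance(config, n_residues = n,
                                         source = chain$source)),
            class = "bfactor_report")
}

#' @export
print.bfactor_report <- function(x, ...) {
  cat(sprintf("B-factor pipeline: %d residues, PCC = %.4f (%s fit)\n",
              nrow(x$table), x$pcc, x$fit$method))
  invisible(x)
}

# modality preprocessing -> connectivity matrix for classification
classification_connectivity <- function(data, config) {
  x <- as.matrix(data$x)
  switch(data$modality,
    eeg = {
      xs <- t(scale(t(x)))  # per-channel standardization
      correlation_connectivity(xs)
    },
    scrna = {
      lx <- log1p(x)
      v <- apply(lx, 2L, var)
      lx <- lx[, v >= 1e-6, drop = FALSE]
      attr(lx, "dropped_genes") <- sum(v < 1e-6)
      a <- build_connectivity(pairwise_distances(lx), config$kernel)
      attr(a, "dropped_genes") <- attr(lx, "dropped_genes")
      a
    },
    image = ,
    generic = {
      red <- if (data$modality == "image") config$reducer(x, 3L) else x
      build_connectivity(pairwise_distances(red), config$kernel)
    },
    stop("unknown modality: ", data$modality))
}

#' Classification pipeline for labelled datasets
#'
#' Modality preprocessing (per-channel standardization plus correlation
#' connectivity for `eeg`; `log(1+x)` transform, removal of genes with
#' variance below 1e-6 and exponential-kernel connectivity for `scrna`;
#' a pluggable 3-dimensional reduction then the kernel for `image`;
#' the kernel directly for `generic`), Laplacian filtration, one shared
#' seeded chaotic run per scale, per-node statistics, and seeded stratified
#' cross-validation with the configured classifier adapter.
#'
#' @param data a `labeled_dataset`.
#' @param config a [pipeline_config()].
#' @return list of class `classification_report`: the `cv_report`,
#'   `features`, and `provenance`.
#' @export
run_classification <- function(data, config = pipeline_config()) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (nlevels(data$labels) < 2L) stop("need at least 2 classes")
  a <- classification_connectivity(data, config)
  fam <- laplacian_filtration(a, config$p)
  # one shared seeded run per scale: node identity within a synchronized
  # cluster is what separates classes (config$protocol overrides)
  protocol <- config$protocol %||% "shared"
  feats <- multiscale_features(fam, config$oscillator,
                               epsilon = config$epsilon_shared,
                               protocol = protocol, h = config$h,
                               steps = config$steps, scheme = config$scheme,
                               record_every = config$record_every,
                               stats = config$stats,
                               transient_fraction =
                                 config$transient_fraction,
                               seed = derive_seed(config$seed, 1L))
  cv <- cross_validate(feats, data$labels, folds = config$folds,
                       seeds = vapply(seq_along(config$cv_seeds),
                                      function(i)
                                        derive_seed(config$seed, 100L + i),
                                      0L),
                       classifier = config$classifier)
  structure(list(cv = cv, features = feats,
                 provenance = provenance(config, modality = data$modality,
                                         n_samples = nrow(data$x),
                                         dropped_genes =
                                           attr(a, "dropped_genes"))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification pipeline\n")
  print(x$cv)
  invisible(x)
}

#' Synchronization-regime demonstration on a point cloud
#'
#' Builds the kernel connectivity and its Laplacian filtration for a point
#' cloud, integrates the coupled Lorenz system at every scale from seeded
#' random initial conditions, and classifies each scale's regime from the
#' time-averaged post-transient synchronization error: `"full"` when the
#' global error falls below `threshold * attractor scale` (the attractor
#' scale is the mean time-rms state magnitude), `"partial"` when a declared
#' node subset passes while the global error does not, `"unsynchronized"`
#' otherwise.
#'
#' @param cloud a [point_cloud()]; an optional `labels` element (as from
#'   [chain_cloud()]) declares the subsets used for the partial diagnosis.
#' @param config a [pipeline_config()]; `epsilon_shared` is the coupling
#'   strength.
#' @param scales which scales to run (default: all `p`).
#' @param steps number of integration steps (default `1e5`).
#' @param threshold relative synchronization threshold (default 1e-2).
#' @param record_every frame thinning for the diagnostics.
#' @return data frame of class `regime_report`: per scale the edge count,
#'   global / subset / cross-set mean errors, the attractor scale and the
#'   regime label.  The trajectories of the last run are attached as
#'   attribute `last_trajectory` for orbit plots.
#' @export
run_pointcloud_demo <- function(cloud, config = pipeline_config(),
                                scales = NULL, steps = 1e5L,
                                threshold = 1e-2, record_every = 10L) {
  stopifnot(inherits(cloud, "point_cloud"))
  d <- pairwise_distances(cloud)
  a <- build_connectivity(d, config$kernel)
  fam <- laplacian_filtration(a, config$p)
  scales <- scales %||% seq_len(fam$p)
  labels <- cloud$labels
  subsets <- if (!is.null(labels)) split(seq_along(labels), labels) else NULL
  rows <- list()
  last_traj <- NULL
  for (k in scales) {
    sys <- coupled_system(config$oscillator, scale_coupling(fam, k),
                          config$epsilon_shared)
    init <- random_initial_state(sys$n, derive_seed(config$seed, 1000L + k))
    traj <- integrate_system(sys, init, h = config$h, steps = steps,
                             scheme = config$scheme,
                             record_every = record_every)
    nrec <- dim(traj$states)[1L]
    window <- seq.int(floor(0.8 * nrec) + 1L, nrec)  # last 20 percent
    scale_est <- mean(sqrt(apply(traj$states[window, , , drop = FALSE]^2,
                                 2L, mean)))
    glob <- mean(sync_error(traj)[window])
    sub_err <- cross_err <- NA_real_
    sub_pass <- FALSE
    if (!is.null(subsets) && length(subsets) >= 2L) {
      errs <- vapply(subsets, function(idx)
        if (length(idx) >= 2L)
          mean(sync_error(traj, nodes = idx)[window]) else NA_real_, 0)
      sub_err <- min(errs, na.rm = TRUE)
      cross_err <- mean(sync_error(traj, nodes = subsets[[1L]],
                                   against = subsets[[2L]])[window])
      sub_pass <- any(errs < threshold * scale_est, na.rm = TRUE)
    }
    regime <- if (glob < threshold * scale_est) "full"
              else if (sub_pass) "partial" else "unsynchronized"
    edges <- sum(fam$laplacians[[k]][upper.tri(fam$laplacians[[k]])] != 0)
    rows[[length(rows) + 1L]] <- data.frame(
      scale = k, edges = edges, global_error = glob,
      subset_error = sub_err, cross_error = cross_err,
      attractor_scale = scale_est, regime = regime,
      stringsAsFactors = FALSE)
    last_traj <- traj
  }
  out <- do.call(rbind, rows)
  attr(out, "last_trajectory") <- last_traj
  attr(out, "provenance") <- provenance(config, steps = steps,
                                        threshold = threshold)
  class(out) <- c("regime_report", "data.frame")
  out
}

#' Read a delimited signal matrix (one channel per column)
#'
#' @param path delimited text file; columns are channels, rows samples.
#' @param sep separator (`""` = whitespace).
#' @param header does the file carry a header row?
#' @return matrix with one channel per row (the orientation
#'   [correlation_connectivity()] expects).
#' @export
read_signals <- function(path, sep = "", header = FALSE) {
  t(as.matrix(read.table(path, sep = sep, header = header)))
}

#' Read an expression matrix with labels
#'
#' Delimited text (cells x genes) or MatrixMarket; labels either in a named
#' column of the table or in a one-label-per-line sidecar file.
#'
#' @param path matrix file (`.mtx` is read with [Matrix::readMM()], cells
#'   as rows).
#' @param labels label column name (delimited input) or sidecar file path.
#' @param sep,header passed to [read.table()] for delimited input.
#' @return a `labeled_dataset` with modality `"scrna"`.
#' @export
read_expression <- function(path, labels, sep = "\t", header = TRUE) {
  if (grepl("\\.mtx$", path)) {
    x <- as.matrix(Matrix::readMM(path))
    lab <- readLines(labels)
  } else {
    tab <- read.table(path, sep = sep, header = header,
                      stringsAsFactors = FALSE)
    if (labels %in% names(tab)) {
      lab <- tab[[labels]]
      x <- as.matrix(tab[, setdiff(names(tab), labels), drop = FALSE])
    } else {
      x <- as.matrix(tab)
      lab <- readLines(labels)
    }
  }
  if (length(lab) != nrow(x)) stop("labels do not align with samples")
  new_labeled_dataset(x, lab, "scrna")
}

#' Write a feature matrix with its provenance sidecar
#'
#' @param feats a `feature_matrix`.
#' @param path output path for the delimited table; the provenance is
#'   written next to it as `<path>.provenance`.
#' @export
write_features <- function(feats, path) {
  write.table(as.data.frame(unclass(feats)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  prov <- attr(feats, "provenance")
  writeLines(paste(names(prov),
                   vapply(prov, function(v) paste(format(v), collapse = " "),
                          ""), sep = ": "),
             paste0(path, ".provenance"))
  invisible(path)
}
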