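#' Default trajectory statistic set
#'
#' Eight statistics per state variable: moment-complete through order four
#' (mean, population standard deviation, skewness, excess-free kurtosis
#' ratio m4/m2^2) plus extremes (min, max), median and root mean square.
#' Skewness and kurtosis of a (numerically) constant series are defined as
#' zero.
#'
#' @return character vector of statistic names.
#' @export
default_statistics <- function() {
  c("mean", "sd", "min", "max", "median", "skewness", "kurtosis", "rms")
}

series_statistic <- function(x, stat) {
  switch(stat,
    mean = mean(x),
    sd = sqrt(mean((x - mean(x))^2)),       # population sd
    min = min(x),
    max = max(x),
    median = median(x),
    skewness = {
      m2 <- mean((x - mean(x))^2)
      if (m2 < .Machine$double.eps) 0 else mean((x - mean(x))^3) / m2^1.5
    },
    kurtosis = {
      m2 <- mean((x - mean(x))^2)
      if (m2 < .Machine$double.eps) 0 else mean((x - mean(x))^4) / m2^2
    },
    rms = sqrt(mean(x^2)),
    stop("unknown statistic: ", stat))
}

# statistics of one node's 3-variable series (T x 3 matrix)
series_statistics <- function(series, stats) {
  out <- numeric(3L * length(stats))
  names(out) <- paste(rep(c("x", "y", "z"), each = length(stats)),
                      rep(stats, 3L), sep = "_")
  k <- 1L
  for (v in 1:3) {
    for (s in stats) {
      out[k] <- series_statistic(series[, v], s)
      k <- k + 1L
    }
  }
  out
}

#' Statistics of one node's trajectory
#'
#' Discards the leading `transient_fraction` of frames, then computes the
#' configured statistics of each of the node's three state variables over
#' the remaining window.
#'
#' @param traj a `trajectory`.
#' @param node node index.
#' @param stats statistic names (see [default_statistics()]).
#' @param transient_fraction fraction of frames dropped from the start,
#'   in `[0, 1)` (default 0.1).
#' @return named numeric vector of length `3 * length(stats)`.
#' @export
trajectory_statistics <- function(traj, node, stats = default_statistics(),
                                  transient_fraction = 0.1) {
  if (transient_fraction < 0 || transient_fraction >= 1)
    stop("transient_fraction must be in [0, 1)")
  nrec <- dim(traj$states)[1L]
  from <- floor(transient_fraction * nrec) + 1L
  if (nrec - from + 1L < 2L) stop("post-transient window too short")
  series <- traj$states[from:nrec, node, , drop = FALSE]
  dim(series) <- c(nrec - from + 1L, 3L)
  series_statistics(series, stats)
}

#' Multiscale chaotic features for every node
#'
#' For each scale `k` of a Laplacian filtration, couples the oscillators
#' through `-L_k`, generates trajectories, and extracts per-node statistics;
#' features are concatenated across scales in `k` order.  Two trajectory
#' protocols are available: `"perturbative"` (one run per node, started from
#' the origin with that node displaced to one; the residue protocol) and
#' `"shared"` (a single seeded random-initial run per scale, each node
#' contributing its own trajectory; the signal/cell/image protocol).  A
#' scale whose integration diverges is dropped from the concatenation with
#' a warning and listed in the provenance, never imputed.
#'
#' @param family a [laplacian_filtration()] result.
#' @param spec an [oscillator_spec()].
#' @param epsilon coupling strength.
#' @param protocol `"perturbative"` or `"shared"`.
#' @param h,steps,scheme,record_every integration controls (see
#'   [integrate_system()]).
#' @param stats statistic set.
#' @param transient_fraction fraction of frames discarded before statistics.
#' @param gamma_inner 3x3 inner coupling matrix.
#' @param seed seed for the shared-protocol initial conditions (mandatory
#'   for that protocol; per-scale seeds are derived from it).
#' @param divergence_bound abort threshold per scale.
#' @return `feature_matrix`: numeric `N x F` matrix with feature names
#'   `k<scale>_<var>_<stat>` and a `provenance` attribute recording the
#'   run configuration and any dropped scales.
#' @export
multiscale_features <- function(family, spec = oscillator_spec(),
                                epsilon = 1, protocol = c("perturbative",
                                                          "shared"),
                                h = 1e-3, steps = 2000L, scheme = "rk4",
                                record_every = 1L,
                                stats = default_statistics(),
                                transient_fraction = 0.1,
                                gamma_inner = diag(3), seed = NULL,
                                divergence_bound = 1e6) {
  stopifnot(inherits(family, "laplacian_family"))
  protocol <- match.arg(protocol)
  if (protocol == "shared" && is.null(seed))
    stop("the shared protocol needs a seed for its initial conditions")
  n <- nrow(family$laplacians[[1L]])
  blocks <- list()
  dropped <- integer(0)
  for (k in seq_len(family$p)) {
    sys <- coupled_system(spec, scale_coupling(family, k), epsilon,
                          gamma_inner)
    block <- tryCatch({
      if (protocol == "perturbative") {
        arr <- perturbative_batch(sys, h = h, steps = steps,
                                  scheme = scheme,
                                  record_every = record_every,
                                  divergence_bound = divergence_bound)
        traj <- new_trajectory(arr, h, scheme, as.integer(record_every))
        t(vapply(seq_len(n), function(i)
          trajectory_statistics(traj, i, stats, transient_fraction),
          numeric(3L * length(stats))))
      } else {
        init <- random_initial_state(n, derive_seed(seed, k))
        traj <- integrate_system(sys, init, h = h, steps = steps,
                                 scheme = scheme,
                                 record_every = record_every,
                                 divergence_bound = divergence_bound)
        t(vapply(seq_len(n), function(i)
          trajectory_statistics(traj, i, stats, transient_fraction),
          numeric(3L * length(stats))))
      }
    }, error = function(e) {
      warning("scale ", k, " dropped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(block)) {
      dropped <- c(dropped, k)
    } else {
      colnames(block) <- paste0("k", k, "_", colnames(block))
      blocks[[length(blocks) + 1L]] <- block
    }
  }
  if (!length(blocks)) stop("every scale diverged; no features produced")
  values <- do.call(cbind, blocks)
  structure(values,
            provenance = list(model = spec$model, pars = spec$pars,
                              epsilon = epsilon, protocol = protocol,
                              h = h, steps = steps, scheme = scheme,
                              record_every = record_every,
                              transient_fraction = transient_fraction,
                              stats = stats, seed = seed,
                              p = family$p, dropped_scales = dropped),
            class = c("feature_matrix", "matrix"))
}

#' Variance-ranked feature reduction
#'
#' Keeps the `k` features with the largest variance (computed on `x`, or on
#' `fit_rows` only to stay leakage-free in cross-validation).  Deterministic
#' tie-break by column order.
#'
#' @param x feature matrix.
#' @param k number of features kept.
#' @param fit_rows optional row subset on which variances are computed.
#' @return the reduced matrix (attribute `kept` holds the column indices).
#' @export
reduce_features <- function(x, k = 30L, fit_rows = NULL) {
  x <- as.matrix(x)
  if (k >= ncol(x)) return(x)
  sub <- if (is.null(fit_rows)) x else x[fit_rows, , drop = FALSE]
  v <- apply(sub, 2L, var)
  keep <- sort(order(-v)[seq_len(k)])
  structure(x[, keep, drop = FALSE], kept = keep)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length `>= 3`, both nonconstant.
#' @return sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant input")
  cor(x, y)
}

#' Per-protein linear B-factor regression
#'
#' Ordinary least squares of experimental B-factors on the (optionally
#' variance-reduced) feature matrix with an intercept, fitted per protein;
#' returns fitted values and the Pearson correlation between fitted and
#' experimental values.  A rank-deficient design falls back to ridge
#' regression with `lambda = 1e-8 * trace(X'X) / F`, recorded in the result.
#'
#' @param features `N x F` numeric matrix (N residues).
#' @param b experimental B-factors, length `N`, finite.
#' @param reduce optional feature count for [reduce_features()] before the
#'   fit.
#' @return object of class `regression_result`: `coefficients` (length
#'   `F + 1`, intercept first), `predictions`, `pcc`, `method`, and `ridge`
#'   (the regularization used, 0 for plain OLS).
#' @export
fit_bfactor_regression <- function(features, b, reduce = NULL) {
  x <- as.matrix(features)
  if (!is.null(reduce)) x <- reduce_features(x, reduce)
  n <- nrow(x)
  if (length(b) != n) stop("b must have one value per row of features")
  if (!all(is.finite(b))) stop("B-factors must be finite")
  if (n <= ncol(x) + 1L)
    stop("need more observations than features + 1 (have ", n, " vs ",
         ncol(x) + 1L, "); reduce the feature set")
  X <- cbind(1, x)
  qrx <- qr(X)
  ridge <- 0
  if (qrx$rank < ncol(X)) {
    ridge <- 1e-8 * sum(diag(crossprod(X))) / ncol(x)
    coef <- solve(crossprod(X) + diag(ridge, ncol(X)), crossprod(X, b))
    method <- "ridge"
  } else {
    coef <- qr.coef(qrx, b)
    method <- "ols"
  }
  pred <- as.numeric(X %*% coef)
  structure(list(coefficients = as.numeric(coef), predictions = pred,
                 pcc = pearson_cc(pred, b), method = method, ridge = ridge),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("B-factor regression (%s): %d coefficients, PCC = %.4f\n",
              x$method, length(x$coefficients), x$pcc))
  invisible(x)
}

#' Balanced accuracy
#'
#' Mean over classes of the per-class recall; equal to plain accuracy on
#' class-balanced data and robust to imbalance otherwise.
#'
#' @param truth true labels (every class must be represented).
#' @param predicted predicted labels of the same length.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label lengths differ")
  if (!is.factor(truth)) truth <- factor(truth)  # keep declared levels
  predicted <- factor(predicted, levels = levels(truth))
  counts <- table(truth)
  if (any(counts == 0))
    stop("class absent from the input: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  recalls <- vapply(levels(truth), function(cl) {
    mean(predicted[truth == cl] == cl, na.rm = FALSE)
  }, 0)
  mean(recalls)
}

#' Random-forest classifier adapter
#'
#' Wraps [ranger::ranger()] behind the pluggable classifier interface
#' `f(train_x, train_y, test_x) -> predicted factor`.  Single-threaded and
#' seeded from the R random stream, so cross-validation runs are
#' reproducible.
#'
#' @param num_trees number of trees.
#' @return a classifier adapter function.
#' @export
classifier_rf <- function(num_trees = 500L) {
  function(train_x, train_y, test_x) {
    fit <- ranger::ranger(
      x = as.data.frame(train_x), y = factor(train_y),
      num.trees = num_trees, num.threads = 1L,
      seed = sample.int(.Machine$integer.max, 1L))
    predict(fit, data = as.data.frame(test_x),
            num.threads = 1L)$predictions
  }
}

#' k-nearest-neighbour classifier adapter
#'
#' @param k neighbourhood size.
#' @return a classifier adapter function wrapping [class::knn()].
#' @export
classifier_knn <- function(k = 5L) {
  function(train_x, train_y, test_x) {
    class::knn(as.matrix(train_x), as.matrix(test_x), factor(train_y), k = k)
  }
}

#' Seeded stratified cross-validation
#'
#' Repeats stratified k-fold cross-validation once per seed: fold labels are
#' assigned within each class from a seeded shuffle, the adapter is trained
#' on the training folds, and balanced accuracy plus plain accuracy are
#' recorded per fold.  Confusion counts are accumulated over all folds and
#' seeds.
#'
#' @param x sample matrix (samples x features).
#' @param labels class labels (every class needs at least `folds` members).
#' @param folds number of folds, `>= 2`.
#' @param seeds integer vector of fold-assignment seeds.
#' @param classifier adapter from [classifier_rf()] / [classifier_knn()] or
#'   any `f(train_x, train_y, test_x)`.
#' @param reduce optional feature count; reduction is fitted on the training
#'   folds only (leakage-free).
#' @return object of class `cv_report`: per-fold `results` data frame,
#'   `summary` (mean/sd of both metrics), and the accumulated `confusion`
#'   matrix (rows = truth).
#' @export
cross_validate <- function(x, labels, folds = 5L, seeds = 1:10,
                           classifier = classifier_rf(), reduce = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  counts <- table(labels)
  if (any(counts < folds))
    stop("class(es) with fewer members than folds: ",
         paste(names(counts)[counts < folds], collapse = ", "),
         "; use fewer folds")
  lv <- levels(labels)
  confusion <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  rows <- list()
  for (seed in seeds) {
    set.seed(seed)
    fold_of <- integer(length(labels))
    for (cl in lv) {
      idx <- which(labels == cl)
      fold_of[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      xt <- x
      if (!is.null(reduce)) xt <- reduce_features(x, reduce, fit_rows = train)
      pred <- classifier(xt[train, , drop = FALSE], labels[train],
                         xt[test, , drop = FALSE])
      pred <- factor(pred, levels = lv)
      confusion <- confusion + unclass(table(labels[test], pred))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, fold = f,
        ba = balanced_accuracy(labels[test], pred),
        acc = mean(pred == labels[test]))
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 summary = list(mean_ba = mean(results$ba),
                                sd_ba = sd(results$ba),
                                mean_acc = mean(results$acc),
                                sd_acc = sd(results$acc)),
                 confusion = confusion, folds = folds, seeds = seeds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation: %d folds x %d seeds\n", x$folds,
              length(x$seeds)))
  cat(sprintf("  balanced accuracy %.4f +/- %.4f\n", x$summary$mean_ba,
              x$summary$sd_ba))
  cat(sprintf("  accuracy          %.4f +/- %.4f\n", x$summary$mean_acc,
              x$summary$sd_acc))
  invisible(x)
}

#' Residue and similarity scores
#'
#' Per-sample diagnostics of multiclass structure, both in `[0, 1]`.  For a
#' sample of class `k`: the similarity score is the mean over its same-class
#' partners of `1 - d / d_max` (`d_max` = largest pairwise distance in the
#' dataset), measuring intra-class cohesion; the residue score is its mean
#' distance to out-of-class samples divided by the dataset-wide maximum of
#' such means, measuring inter-class separation.  Degenerate datasets where
#' all samples coincide score similarity 1 and residue 0.
#'
#' @param x sample matrix (samples x features).
#' @param labels class labels (`>= 2` classes, no singleton class).
#' @param predicted optional predicted labels carried into the output.
#' @return data frame with columns `residue`, `similarity`, `label` and
#'   (when given) `predicted`.
#' @export
rs_scores <- function(x, labels, predicted = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L))
    stop("singleton class(es): similarity undefined")
  dmat <- as.matrix(dist(x))
  dmax <- max(dmat)
  n <- nrow(x)
  sim <- res <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    other <- which(labels != labels[i])
    sim[i] <- if (dmax == 0) 1 else mean(1 - dmat[i, same] / dmax)
    res[i] <- mean(dmat[i, other])
  }
  rmax <- max(res)
  res <- if (rmax == 0) rep(0, n) else res / rmax
  out <- data.frame(residue = res, similarity = sim, label = labels)
  if (!is.null(predicted)) out$predicted <- factor(predicted)
  out
}
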