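# Rotation forest: each tree sees the data after a block-diagonal
# rotation assembled from PCA bases fitted on random disjoint feature
# subsets (local PCA on a subsample of rows). Trees are Gini decision
# trees delegated to ranger; votes are averaged leaf probabilities.
#
# When the requested subset count K reaches the feature count every
# subset is a singleton, every local PCA block is the scalar +1, and all
# rotations collapse to the identity. The ensemble is then exactly a
# bagged forest of Gini trees on the unrotated data, which is fitted in
# a single ranger call; with non-trivial blocks each tree is fitted
# separately on its own rotated copy. In both cases per-tree instance
# subsampling (bootstrap_fraction, without replacement) supplies the
# ensemble's diversity.

#' Build one block-diagonal PCA rotation
#'
#' For every subset in the feature partition, a subsample of
#' `ceiling(bootstrap_fraction * n)` distinct rows is drawn, the full PCA
#' basis of the subset's columns on those rows is computed, and its
#' component vectors form the subset's diagonal block. Degenerate
#' directions (zero-variance columns) keep an orthonormal completion of
#' the basis, so every block — and hence the whole matrix — stays
#' block-orthonormal and norm-preserving. Rotated data is `x %*% R`.
#'
#' @param x Training matrix `n x d`.
#' @param partition List of disjoint integer vectors covering `1:d`.
#' @param bootstrap_fraction Fraction of rows per subset sample, in (0, 1\];
#'   1 uses all rows, making the single-subset rotation the exact global
#'   PCA basis.
#' @return Orthonormal `d x d` rotation matrix aligned to the original
#'   feature order. Uses the current RNG state (seed upstream).
#' @export
build_rotation <- function(x, partition, bootstrap_fraction = 0.75) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  idx <- sort(as.integer(unlist(partition, use.names = FALSE)))
  if (!identical(idx, seq_len(d)))
    stop("partition must cover every feature exactly once")
  stopifnot(bootstrap_fraction > 0, bootstrap_fraction <= 1)
  m <- ceiling(bootstrap_fraction * n)
  R <- matrix(0, d, d)
  for (sub in partition) {
    if (length(sub) == 1L) { R[sub, sub] <- 1; next }  # PCA of one column
    rows <- if (m >= n) seq_len(n) else sample.int(n, m)
    cv <- cov(x[rows, sub, drop = FALSE])
    # eigen of a rank-deficient covariance still yields an orthonormal
    # basis (identity block in the fully degenerate case)
    ev <- eigen(cv, symmetric = TRUE)
    R[sub, sub] <- ev$vectors
  }
  R
}

#' Train a rotation forest
#'
#' For each of `n_classifiers` trees the `d` features are randomly
#' partitioned into `min(K, d)` subsets of near-equal size, a rotation is
#' built with [build_rotation()], and a Gini decision tree (grown without
#' a depth cap by default, all features searched at every split) is
#' fitted on the rotated data restricted to a per-tree subsample of
#' `ceiling(bootstrap_fraction * n)` rows drawn without replacement.
#' When `K` is at least the feature count (as with the default `K = 200`
#' on 84 PCA features, which a message reports as clamped) the subsets
#' are singletons, every rotation is the identity, and the per-tree
#' instance subsample is the ensemble's only source of diversity;
#' `bootstrap_fraction = 1` disables subsampling so every tree sees all
#' rows.
#'
#' @param x Feature matrix `n x d`, `n >= 4`.
#' @param y Binary labels (0/1, logical, or 2-level factor); both classes
#'   must be present.
#' @param n_classifiers Number of trees (default 139).
#' @param K Requested number of feature subsets (default 200, clamped to
#'   `d`).
#' @param bootstrap_fraction Row fraction for the local PCAs and the
#'   per-tree subsample (default 0.75).
#' @param max_depth Optional depth cap for the trees (`NULL` = unlimited).
#' @param seed Integer seed; the same seed gives an identical model.
#' @return List of class `"rotation_forest"`; when rotations are
#'   non-trivial, per-tree `partition`, `rotation` and fitted `tree`.
#' @export
rotation_forest <- function(x, y, n_classifiers = 139, K = 200,
                            bootstrap_fraction = 0.75, max_depth = NULL,
                            seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 4) stop("need at least 4 samples")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    stop("rotation forest requires both classes in y")
  stopifnot(n_classifiers >= 1, K >= 1)
  k_eff <- min(K, d)
  if (k_eff < K)
    message(sprintf("K = %d exceeds the %d available features; clamped to %d (singleton subsets, identity rotations)",
                    K, d, k_eff))
  colnames(x) <- paste0("f", seq_len(d))
  max_depth <- if (is.null(max_depth)) 0L else as.integer(max_depth)

  if (k_eff == d) {
    # all-singleton partition: every rotation is exactly the identity,
    # so the whole ensemble is one bagged Gini forest
    forest <- ranger::ranger(
      x = x, y = y, num.trees = n_classifiers, mtry = d,
      sample.fraction = bootstrap_fraction, replace = FALSE,
      min.node.size = 1, max.depth = max_depth, probability = TRUE,
      num.threads = 1, seed = derive_seed(seed, 0L), verbose = FALSE)
    return(structure(list(engine = "bagged", forest = forest, d = d,
                          classes = levels(y), positive = levels(y)[2],
                          n_classifiers = n_classifiers),
                     class = "rotation_forest"))
  }

  trees <- with_seed(seed, lapply(seq_len(n_classifiers), function(t) {
    part <- split(sample.int(d), rep_len(seq_len(k_eff), d))
    R <- build_rotation(x, part, bootstrap_fraction)
    z <- x %*% R
    colnames(z) <- colnames(x)
    fit <- ranger::ranger(
      x = z, y = y, num.trees = 1, mtry = d,
      sample.fraction = bootstrap_fraction, replace = FALSE,
      min.node.size = 1, max.depth = max_depth, probability = TRUE,
      num.threads = 1, seed = derive_seed(seed, t), verbose = FALSE)
    list(partition = part, rotation = R, tree = fit)
  }))
  structure(list(engine = "rotated", trees = trees, d = d,
                 classes = levels(y), positive = levels(y)[2],
                 n_classifiers = n_classifiers),
            class = "rotation_forest")
}

#' Predict positive-class scores with a rotation forest
#'
#' Each tree scores the rotated input with its leaf's positive-class
#' probability; the forest score is the mean over trees, in \[0, 1\].
#'
#' @param object A [rotation_forest()] model.
#' @param newdata Feature matrix with the training feature width.
#' @param ... Unused.
#' @return Numeric vector of positive-class scores.
#' @export
predict.rotation_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop(sprintf("feature width %d does not match the trained width %d",
                 ncol(newdata), object$d))
  colnames(newdata) <- paste0("f", seq_len(object$d))
  if (object$engine == "bagged") {
    p <- predict(object$forest, newdata, num.threads = 1)$predictions
    return(unname(p[, object$positive]))
  }
  scores <- vapply(object$trees, function(tr) {
    z <- newdata %*% tr$rotation
    colnames(z) <- colnames(newdata)
    p <- predict(tr$tree, z, num.threads = 1)$predictions
    unname(p[, object$positive])
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1) scores <- matrix(scores, nrow = 1)
  rowMeans(scores)
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("rotation forest: %d trees on %d features (%s engine, classes %s)\n",
              x$n_classifiers, x$d, x$engine,
              paste(x$classes, collapse = "/")))
  invisible(x)
}
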