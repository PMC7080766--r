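# PCA reduction of the autoencoder codes (default 100 -> 84 dimensions).
# Thin wrapper over base R's prcomp with a deterministic sign convention.

#' Fit a PCA reduction
#'
#' Components are the top-`k` eigenvectors of the centered covariance,
#' ordered by descending eigenvalue and sign-fixed so that each
#' component's largest-magnitude loading is positive (removes the sign
#' ambiguity of eigenvectors, making fits reproducible).
#'
#' @param x Numeric matrix `n x d`, `n >= 2`.
#' @param k Output dimension (default 84); must satisfy
#'   `k <= min(n - 1, d)`.
#' @return List of class `"pca_model"`: `components` (`k x d`, orthonormal
#'   rows), `mean` (length `d`), `variances` (eigenvalues, length `k`),
#'   `k`.
#' @export
pca_fit <- function(x, k = 84) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2) stop("PCA needs at least 2 rows")
  if (k > min(n - 1, d))
    stop(sprintf("k = %d exceeds min(n - 1, d) = %d", k, min(n - 1, d)))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])  # k x d
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(components = unname(comp), mean = unname(pc$center),
                 variances = pc$sdev[seq_len(k)]^2, k = as.integer(k)),
            class = "pca_model")
}

#' Project samples onto fitted principal components
#'
#' @param model A [pca_fit()] model.
#' @param x Matrix `n x d` in the original feature space.
#' @return Matrix `n x k` of centered projections.
#' @export
pca_transform <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop("feature width does not match the fitted PCA")
  sweep(x, 2, model$mean) %*% t(model$components)
}
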