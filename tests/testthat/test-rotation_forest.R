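# Rotation forest: block-orthonormal rotations, ensemble behavior,
# determinism, and the single-tree reduction oracle.

make_blobs <- function(n_per = 40, sep = 4, seed = 0) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  list(x = x, y = rep(c(0, 1), each = n_per))
}

test_that("rotations are block-diagonal and norm-preserving", {
  set.seed(1)
  x <- matrix(rnorm(30 * 4), 30, 4)
  R <- build_rotation(x, list(1:2, 3:4), bootstrap_fraction = 1)
  expect_equal(R[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(R[3:4, 1:2], matrix(0, 2, 2))
  expect_equal(crossprod(R), diag(4), tolerance = 1e-9)
  for (i in 1:10) {
    v <- rnorm(4)
    expect_equal(sqrt(sum((R %*% v)^2)), sqrt(sum(v^2)), tolerance = 1e-9)
  }
  expect_error(build_rotation(x, list(1:2, 2:4)), "exactly once")
})

test_that("a single full subset yields the global PCA basis", {
  set.seed(2)
  x <- matrix(rnorm(8 * 4), 8, 4)
  x[, 2] <- 2 * x[, 1] + rnorm(8, sd = 0.1)   # correlated features
  R <- build_rotation(x, list(1:4), bootstrap_fraction = 1)
  rotated_cov <- cov(x %*% R)
  off <- rotated_cov; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-10)             # diagonal covariance
  expect_equal(sort(diag(rotated_cov), decreasing = TRUE),
               unname(diag(rotated_cov)), tolerance = 1e-12)
})

test_that("degenerate (constant) columns fall back to identity directions", {
  x <- cbind(rnorm(20), 1, 1)
  R <- build_rotation(x, list(1:3), bootstrap_fraction = 1)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
  expect_false(any(is.na(R)))
})

test_that("the forest separates linearly separable blobs", {
  b <- make_blobs()
  suppressMessages(rf <- rotation_forest(b$x, b$y, n_classifiers = 5,
                                         K = 200, seed = 0))
  expect_equal(as.integer(predict(rf, b$x) >= 0.5), b$y)
  expect_true(all(predict(rf, b$x) >= 0 & predict(rf, b$x) <= 1))
})

test_that("K above the feature count is clamped with a message", {
  b <- make_blobs()
  expect_message(rotation_forest(b$x, b$y, n_classifiers = 3, K = 200,
                                 seed = 0),
                 "clamped")
  expect_silent(rf <- rotation_forest(b$x, b$y, n_classifiers = 3, K = 1,
                                      seed = 0))
  expect_equal(rf$engine, "rotated")
  expect_length(rf$trees, 3)
  for (tr in rf$trees) {
    covered <- sort(unlist(tr$partition, use.names = FALSE))
    expect_equal(covered, 1:2)
    expect_equal(crossprod(tr$rotation), diag(2), tolerance = 1e-9)
  }
})

test_that("the same seed reproduces the model and its predictions", {
  b <- make_blobs(n_per = 25)
  suppressMessages({
    m1 <- rotation_forest(b$x, b$y, n_classifiers = 7, seed = 5)
    m2 <- rotation_forest(b$x, b$y, n_classifiers = 7, seed = 5)
    m3 <- rotation_forest(b$x, b$y, n_classifiers = 7, seed = 6)
  })
  expect_identical(predict(m1, b$x), predict(m2, b$x))
  expect_false(identical(predict(m1, b$x), predict(m3, b$x)))
})

test_that("one tree with one full subset equals a tree on PCA-rotated data", {
  set.seed(10)
  n <- 60
  x <- matrix(rnorm(n * 5), n, 5)
  y <- as.integer(x[, 1] + 0.5 * x[, 3] + rnorm(n, sd = 0.3) > 0)
  rf <- rotation_forest(x, y, n_classifiers = 1, K = 1,
                        bootstrap_fraction = 1, seed = 3)
  R <- rf$trees[[1]]$rotation
  z <- x %*% R
  colnames(z) <- paste0("f", 1:5)
  oracle <- ranger::ranger(x = z, y = factor(y), num.trees = 1, mtry = 5,
                           sample.fraction = 1, replace = FALSE,
                           min.node.size = 1, probability = TRUE,
                           num.threads = 1,
                           seed = repoforest:::derive_seed(3, 1),
                           verbose = FALSE)
  want <- predict(oracle, z, num.threads = 1)$predictions[, "1"]
  expect_equal(predict(rf, x), unname(want), tolerance = 1e-12)
})

test_that("ensemble accuracy does not degrade with more trees", {
  # statistical check over seeds; allow one violation in twenty
  violations <- 0
  for (s in 1:20) {
    b <- make_blobs(n_per = 20, sep = 2.2, seed = s)
    suppressMessages({
      small <- rotation_forest(b$x, b$y, n_classifiers = 2, seed = s)
      big <- rotation_forest(b$x, b$y, n_classifiers = 25, seed = s)
    })
    acc <- function(m) mean(as.integer(predict(m, b$x) >= 0.5) == b$y)
    if (acc(big) < acc(small)) violations <- violations + 1
  }
  expect_lte(violations, 1)
})

test_that("prediction validates width and batches consistently", {
  b <- make_blobs(n_per = 15)
  suppressMessages(rf <- rotation_forest(b$x, b$y, n_classifiers = 4,
                                         seed = 2))
  expect_error(predict(rf, matrix(0, 2, 3)), "width")
  batch <- predict(rf, b$x[1:4, ])
  solo <- vapply(1:4, function(i) predict(rf, b$x[i, , drop = FALSE]),
                 numeric(1))
  expect_equal(batch, solo)
  expect_error(suppressMessages(rotation_forest(b$x, rep(1, nrow(b$x)))),
               "both classes")
})
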