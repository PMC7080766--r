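# End-to-end pipeline: labeled pair assembly with negative sampling,
# classification metrics, ROC/AUC, stratified k-fold cross-validation
# (leakage-safe by default: GIP kernels and similarity fusion are
# recomputed per fold with the test fold's positives masked out of the
# association matrix), and the disease-masking ranking mode used for
# case studies.

#' Default pipeline configuration
#'
#' Collects every tunable of the similarity, feature-learning and
#' classifier stages with its default: logistic slope/intercept `c = -15`,
#' `f = log(999)`; semantic decay `psi = 0.5`; GIP bandwidth
#' `theta_prime = 0.5`; clustering penalty 2, min cohesion 0.3, min size
#' 3, overlap threshold 0.8; autoencoder hidden width 100, sparsity
#' target `rho = 0.05`, weight `gamma = 1e-6`, 100 epochs of batch-64
#' adadelta; PCA output width 84; rotation forest with 139 trees and
#' `K = 200` requested subsets.
#'
#' @param ... Named overrides of any listed element.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    c = -15, f = log(999), psi = 0.5, theta_prime = 0.5,
    penalty_per_node = 2, min_cohesion = 0.3, min_size = 3,
    overlap_threshold = 0.8,
    s2 = 100, rho = 0.05, gamma = 1e-6, epochs = 100, batch_size = 64,
    adadelta_decay = 0.95, adadelta_eps = 1e-6, full_batch_rho = FALSE,
    pca_dim = 84,
    n_classifiers = 139, K = 200, bootstrap_fraction = 0.75,
    max_depth = NULL,
    negative_ratio = 1, threshold = 0.5)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Assemble a labeled pair set
#'
#' All 1-entries of the association matrix become positives; negatives
#' are drawn uniformly without replacement from the 0-entries (unknown
#' pairs), `ceiling(negative_ratio * n_pos)` of them.
#'
#' @param assoc An [association_matrix()].
#' @param negative_ratio Negatives per positive (default 1).
#' @param seed Integer seed; same seed, same pair set.
#' @param exclude_diseases Optional disease ids whose pairs are excluded
#'   from negative sampling (used by the ranking mode for the masked
#'   query disease).
#' @return Data frame with columns `disease_index`, `drug_index`, `label`
#'   (integer 0/1) and `provenance` (`"known_positive"` /
#'   `"sampled_negative"`).
#' @export
assemble_pairs <- function(assoc, negative_ratio = 1, seed = 1,
                           exclude_diseases = NULL) {
  a <- unclass(assoc)
  pos <- which(a == 1, arr.ind = TRUE)
  zero <- which(a == 0, arr.ind = TRUE)
  if (!is.null(exclude_diseases)) {
    drop <- rownames(a)[zero[, 1]] %in% exclude_diseases
    zero <- zero[!drop, , drop = FALSE]
  }
  n_neg <- ceiling(negative_ratio * nrow(pos))
  if (nrow(zero) < n_neg)
    stop(sprintf("only %d unknown pairs available for %d requested negatives",
                 nrow(zero), n_neg))
  neg <- with_seed(seed, zero[sample.int(nrow(zero), n_neg), , drop = FALSE])
  data.frame(
    disease_index = c(pos[, 1], neg[, 1]),
    drug_index = c(pos[, 2], neg[, 2]),
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
    provenance = rep(c("known_positive", "sampled_negative"),
                     c(nrow(pos), nrow(neg))),
    row.names = NULL)
}

#' Classification metrics from binary predictions
#'
#' Confusion counts plus precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2PR/(P+R)` and accuracy `(TP+TN)/total`. A metric with a zero
#' denominator is reported as 0 and named in `undefined`.
#'
#' @param labels,predictions Equal-length binary vectors.
#' @return List with `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `f1`,
#'   `accuracy`, `undefined`.
#' @export
compute_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(unique(labels)) < 2)
    stop("labels must contain both classes")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  undefined <- character(0)
  ratio <- function(num, den, nm) {
    if (den == 0) { undefined <<- c(undefined, nm); 0 } else num / den
  }
  p <- ratio(tp, tp + fp, "precision")
  r <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * p * r, p + r, "f1")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = p, recall = r, f1 = f1,
       accuracy = (tp + tn) / length(labels), undefined = undefined)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct score values as thresholds, accumulating
#' true/false positive rates; the AUC is the trapezoidal integral of the
#' curve. Tied positive-negative score pairs contribute 1/2 each, so the
#' value equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`, and any strictly monotone transform of the scores
#' leaves it unchanged.
#'
#' @param labels Binary vector with both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return List with `auc` and `curve` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop("labels and scores differ in length")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # group ties: one curve point per distinct score
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' The labeled pair set is split into `n_folds` stratified folds
#' (positives and negatives spread evenly). For every fold, in the
#' default leakage-safe mode, the test fold's positive cells are zeroed
#' in the association matrix before the GIP kernels, cluster enhancement
#' and fusion are recomputed, so no test association leaks into the
#' features; the autoencoder, PCA and rotation forest are fitted on the
#' training fold only and the held-out fold is scored. `paper_mode =
#' TRUE` instead computes the similarity profiles once from the full
#' matrix (the optimistic variant in which test associations inform the
#' kernels).
#'
#' @param assoc An [association_matrix()].
#' @param drug_sim Raw drug structural [similarity_matrix()].
#' @param dag A [disease_dag()] or `NULL` (identity semantic similarity).
#' @param config A [pipeline_config()].
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed driving pair sampling, fold assignment and
#'   every model fit.
#' @param paper_mode Compute similarities once from the full matrix
#'   instead of per fold.
#' @param permute_labels Randomly permute the pair labels before folding
#'   (null-signal control; AUC should sit near 0.5).
#' @return List of class `"cv_report"`: `per_fold` (data frame of
#'   accuracy, precision, recall, f1, auc per fold), `mean`, `sd`,
#'   `roc` (per-fold curves), `pairs`, `config`.
#' @export
cross_validate <- function(assoc, drug_sim, dag = NULL,
                           config = pipeline_config(), n_folds = 10,
                           seed = 1, paper_mode = FALSE,
                           permute_labels = FALSE) {
  if (n_folds < 2) stop("n_folds must be at least 2")
  pairs <- assemble_pairs(assoc, config$negative_ratio, seed)
  if (permute_labels)
    pairs$label <- with_seed(derive_seed(seed, 999L),
                             sample(pairs$label))
  fold <- integer(nrow(pairs))
  fold[pairs$label == 1] <- with_seed(derive_seed(seed, 1L),
    sample(rep_len(seq_len(n_folds), sum(pairs$label == 1))))
  fold[pairs$label == 0] <- with_seed(derive_seed(seed, 2L),
    sample(rep_len(seq_len(n_folds), sum(pairs$label == 0))))
  if (any(tabulate(fold[pairs$label == 1], n_folds) == 0) ||
      any(tabulate(fold[pairs$label == 0], n_folds) == 0))
    stop("a fold lost one of the classes; use fewer folds")

  semantic_base <- NULL
  sims_full <- NULL
  if (paper_mode) {
    sims_full <- sim_profiles_from_config(assoc, drug_sim, dag, config)
    semantic_base <- sims_full$semantic_base
  }

  fold_rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- fold == k
    sims <- if (paper_mode) sims_full else {
      masked <- mask_positives(assoc, pairs[test & pairs$label == 1, ])
      s <- sim_profiles_from_config(masked, drug_sim, dag, config,
                                    semantic_base = semantic_base)
      semantic_base <- s$semantic_base   # DAG part is fold-invariant; cache
      s
    }
    x_tr <- pair_features(sims$drug, sims$disease,
                          pairs$drug_index[!test], pairs$disease_index[!test])
    x_te <- pair_features(sims$drug, sims$disease,
                          pairs$drug_index[test], pairs$disease_index[test])
    fold_seed <- derive_seed(seed, 10L + k)
    sae <- sae_train(x_tr, s2 = config$s2, rho = config$rho,
                     gamma = config$gamma, epochs = config$epochs,
                     batch_size = config$batch_size,
                     adadelta_decay = config$adadelta_decay,
                     adadelta_eps = config$adadelta_eps,
                     full_batch_rho = config$full_batch_rho,
                     seed = fold_seed)
    h_tr <- sae_encode(sae, x_tr)
    pca <- pca_fit(h_tr, k = min(config$pca_dim, min(nrow(h_tr) - 1,
                                                     ncol(h_tr))))
    z_tr <- pca_transform(pca, h_tr)
    z_te <- pca_transform(pca, sae_encode(sae, x_te))
    rf <- rotation_forest(z_tr, pairs$label[!test],
                          n_classifiers = config$n_classifiers,
                          K = config$K,
                          bootstrap_fraction = config$bootstrap_fraction,
                          max_depth = config$max_depth, seed = fold_seed)
    scores <- predict(rf, z_te)
    m <- compute_metrics(pairs$label[test],
                         as.integer(scores >= config$threshold))
    roc <- roc_auc(pairs$label[test], scores)
    fold_rows[[k]] <- list(metrics = m, auc = roc$auc, curve = roc$curve)
  }
  per_fold <- data.frame(
    fold = seq_len(n_folds),
    accuracy = vapply(fold_rows, function(z) z$metrics$accuracy, 0),
    precision = vapply(fold_rows, function(z) z$metrics$precision, 0),
    recall = vapply(fold_rows, function(z) z$metrics$recall, 0),
    f1 = vapply(fold_rows, function(z) z$metrics$f1, 0),
    auc = vapply(fold_rows, function(z) z$auc, 0))
  agg <- per_fold[, -1]
  structure(list(per_fold = per_fold,
                 mean = colMeans(agg),
                 sd = apply(agg, 2, sd),
                 roc = lapply(fold_rows, `[[`, "curve"),
                 pairs = cbind(pairs, fold = fold),
                 config = config),
            class = "cv_report")
}

sim_profiles_from_config <- function(assoc, drug_sim, dag, config,
                                     semantic_base = NULL) {
  compute_similarity_profiles(
    assoc, drug_sim, dag,
    c = config$c, f = config$f, psi = config$psi,
    theta_prime = config$theta_prime,
    penalty_per_node = config$penalty_per_node,
    min_cohesion = config$min_cohesion, min_size = config$min_size,
    overlap_threshold = config$overlap_threshold,
    semantic_base = semantic_base)
}

# Zero the association cells listed in `pairs` (a data frame with
# disease_index / drug_index); used to mask test-fold positives.
mask_positives <- function(assoc, pairs) {
  a <- unclass(assoc)
  cls <- class(assoc)
  if (nrow(pairs))
    a[cbind(pairs$disease_index, pairs$drug_index)] <- 0L
  class(a) <- cls
  a
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation on %d pairs\n",
              nrow(x$per_fold), nrow(x$pairs)))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Rank candidate drugs for a disease (case-study mode)
#'
#' Removes every association of the query disease from the matrix,
#' rebuilds the similarity profiles from the masked matrix, trains the
#' autoencoder + PCA + rotation forest on all remaining labeled pairs
#' (the query disease's unknown pairs are excluded from negative
#' sampling), scores every drug against the query disease, and returns
#' the top-`top_k` drugs by descending score with ties broken by drug id.
#'
#' @inheritParams cross_validate
#' @param disease_id Query disease (must be a row of `assoc`).
#' @param top_k Number of drugs to return (default 20).
#' @return Data frame `drug_id`, `disease_id`, `score`, `rank`, plus the
#'   full score vector as attribute `"all_scores"`.
#' @export
rank_drugs_for_disease <- function(assoc, drug_sim, dag = NULL, disease_id,
                                   config = pipeline_config(), top_k = 20,
                                   seed = 1) {
  if (!disease_id %in% rownames(assoc))
    stop(sprintf("unknown disease '%s'", disease_id))
  d_idx <- match(disease_id, rownames(assoc))
  masked <- unclass(assoc)
  masked[d_idx, ] <- 0L
  class(masked) <- class(assoc)
  sims <- sim_profiles_from_config(masked, drug_sim, dag, config)
  pairs <- assemble_pairs(masked, config$negative_ratio, seed,
                          exclude_diseases = disease_id)
  x_tr <- pair_features(sims$drug, sims$disease,
                        pairs$drug_index, pairs$disease_index)
  sae <- sae_train(x_tr, s2 = config$s2, rho = config$rho,
                   gamma = config$gamma, epochs = config$epochs,
                   batch_size = config$batch_size,
                   adadelta_decay = config$adadelta_decay,
                   adadelta_eps = config$adadelta_eps,
                   full_batch_rho = config$full_batch_rho, seed = seed)
  h_tr <- sae_encode(sae, x_tr)
  pca <- pca_fit(h_tr, k = min(config$pca_dim,
                               min(nrow(h_tr) - 1, ncol(h_tr))))
  rf <- rotation_forest(pca_transform(pca, h_tr), pairs$label,
                        n_classifiers = config$n_classifiers, K = config$K,
                        bootstrap_fraction = config$bootstrap_fraction,
                        max_depth = config$max_depth, seed = seed)
  n_drugs <- ncol(assoc)
  x_all <- pair_features(sims$drug, sims$disease,
                         seq_len(n_drugs), rep(d_idx, n_drugs))
  scores <- predict(rf, pca_transform(pca, sae_encode(sae, x_all)))
  names(scores) <- colnames(assoc)
  ord <- order(-scores, names(scores))
  top <- head(ord, top_k)
  out <- data.frame(drug_id = names(scores)[top],
                    disease_id = disease_id,
                    score = unname(scores[top]),
                    rank = seq_along(top),
                    row.names = NULL)
  attr(out, "all_scores") <- scores
  out
}
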