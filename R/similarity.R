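# Similarity construction: logistic rescaling of raw similarities,
# ClusterONE-style cohesive clustering on the shared-association network,
# MeSH DAG semantic similarity, Gaussian interaction profile (GIP) kernels,
# and the fusion rule that fills GIP gaps with the structural/semantic
# fallback.

#' Logistic similarity rescaling
#'
#' Maps a raw similarity `x` through `L(x) = 1 / (1 + exp(c*x + f))`, a
#' sharpened sigmoid that pushes weak similarities (below about 0.3)
#' towards 0 and strong ones (above about 0.6) towards 1. With the default
#' slope `c = -15` and intercept `f = log(999)`, `L(0) = 0.001` and
#' `L(1)` is approximately 0.9997.
#'
#' @param x Numeric vector or matrix of raw similarities in \[0, 1\].
#' @param c Negative slope (default -15).
#' @param f Positive intercept (default `log(999)`, natural log).
#' @return Transformed values, same shape as `x`.
#' @export
logistic_curve <- function(x, c = -15, f = log(999)) {
  stopifnot(c < 0, f > 0)
  1 / (1 + exp(c * x + f))
}

#' Apply the logistic rescaling to a similarity matrix
#'
#' Off-diagonal entries pass through [logistic_curve()]; the diagonal is
#' set to 1. Symmetry is preserved.
#'
#' @param sim A [similarity_matrix()].
#' @inheritParams logistic_curve
#' @return A similarity matrix of the same kind.
#' @export
adjust_logistic <- function(sim, c = -15, f = log(999)) {
  out <- logistic_curve(unclass(sim), c = c, f = f)
  diag(out) <- 1
  similarity_matrix(out, rownames(sim), kind = attr(sim, "kind"))
}

#' Shared-association weighted network
#'
#' Builds the weighted graph whose nodes are drugs (or diseases) and whose
#' edge weight is the number of diseases (drugs) associated with both
#' endpoints: for drugs, the dot product of the two columns of the
#' association matrix. The diagonal is zero.
#'
#' @param assoc An [association_matrix()].
#' @param axis `"drugs"` or `"diseases"`.
#' @return Symmetric non-negative weight matrix with a zero diagonal.
#' @export
shared_association_graph <- function(assoc, axis = c("drugs", "diseases")) {
  axis <- match.arg(axis)
  a <- unclass(assoc)
  storage.mode(a) <- "double"
  w <- if (axis == "drugs") crossprod(a) else tcrossprod(a)
  diag(w) <- 0
  w
}

#' Cohesion of a node set in a weighted graph
#'
#' `W_in / (W_in + W_bound + P)` where `W_in` is the total weight of edges
#' internal to the set, `W_bound` the total weight of edges crossing its
#' boundary, and `P = penalty_per_node * |members|`. Returns 0 when the
#' denominator is 0.
#'
#' @param graph Symmetric weight matrix with zero diagonal.
#' @param members Integer node indices (1-based), at least one.
#' @param penalty_per_node Non-negative per-node penalty (default 2).
#' @return Cohesion in \[0, 1\].
#' @export
cluster_cohesion <- function(graph, members, penalty_per_node = 2) {
  n <- nrow(graph)
  members <- as.integer(members)
  if (length(members) < 1 || any(members < 1 | members > n))
    stop("member index out of range")
  inside <- logical(n)
  inside[members] <- TRUE
  sub <- graph[members, , drop = FALSE]
  w_in <- sum(sub[, members, drop = FALSE]) / 2
  w_bound <- sum(sub[, !inside, drop = FALSE])
  denom <- w_in + w_bound + penalty_per_node * length(members)
  if (denom == 0) return(0)
  w_in / denom
}

#' Greedy cohesive clustering of a weighted graph
#'
#' ClusterONE-style search for overlapping cohesive groups. Clusters are
#' seeded from the unclaimed node of highest weighted degree and grown
#' greedily: at each step the single node addition or removal that most
#' increases cohesion is applied, until no step increases it. Grown
#' clusters are kept when their cohesion reaches `min_cohesion` and their
#' size reaches `min_size` (relaxed to 2 on graphs with fewer than 6
#' nodes); pairs whose overlap score `|V1 n V2|^2 / (|V1| |V2|)` exceeds
#' `overlap_threshold` are merged. Ties break towards the lowest node
#' index, making the result deterministic.
#'
#' @inheritParams cluster_cohesion
#' @param min_cohesion Minimum cohesion to keep a cluster (default 0.3).
#' @param min_size Minimum cluster size (default 3).
#' @param overlap_threshold Overlap score above which clusters merge
#'   (default 0.8).
#' @return List of clusters, each a list with `members` (sorted integer
#'   indices) and `cohesion`.
#' @export
cluster_one <- function(graph, penalty_per_node = 2, min_cohesion = 0.3,
                        min_size = 3, overlap_threshold = 0.8) {
  n <- nrow(graph)
  if (n == 0) return(list())
  if (n < 6) min_size <- min(min_size, 2L)
  degree <- rowSums(graph)
  claimed <- degree == 0          # isolated nodes cannot seed a cluster
  clusters <- list()
  while (!all(claimed)) {
    cand <- which(!claimed)
    seed <- cand[which.max(degree[cand])]
    members <- grow_cluster(graph, seed, penalty_per_node)
    claimed[members] <- TRUE
    claimed[seed] <- TRUE    # growth may drop the seed itself; never reseed it
    coh <- cluster_cohesion(graph, members, penalty_per_node)
    if (coh >= min_cohesion && length(members) >= min_size)
      clusters[[length(clusters) + 1L]] <- list(members = sort(members),
                                                cohesion = coh)
  }
  merge_overlapping(graph, clusters, penalty_per_node, overlap_threshold)
}

# Greedy add-or-remove growth from a seed; strict cohesion increase only,
# lowest-index tie-break, so the trace is finite and deterministic.
grow_cluster <- function(graph, seed, penalty) {
  n <- nrow(graph)
  inside <- logical(n)
  inside[seed] <- TRUE
  # incremental state: w_in, w_bound
  w_in <- 0
  w_bound <- sum(graph[seed, ])
  size <- 1L
  coh <- function(wi, wb, s) {
    d <- wi + wb + penalty * s
    if (d == 0) 0 else wi / d
  }
  current <- coh(w_in, w_bound, size)
  repeat {
    best_gain <- 0; best_node <- 0L; best_add <- NA
    # additions: only neighbours of the cluster can raise w_in
    link <- colSums(graph[inside, , drop = FALSE])
    outside <- which(!inside & link > 0)
    for (v in outside) {
      wi <- w_in + link[v]
      wb <- w_bound - link[v] + (sum(graph[v, ]) - link[v])
      g <- coh(wi, wb, size + 1L) - current
      if (g > best_gain + 1e-15) { best_gain <- g; best_node <- v; best_add <- TRUE }
    }
    if (size > 1L) {
      for (v in which(inside)) {
        lv <- link[v]                       # weight from v into the cluster
        wi <- w_in - lv
        wb <- w_bound - (sum(graph[v, ]) - lv) + lv
        g <- coh(wi, wb, size - 1L) - current
        if (g > best_gain + 1e-15) { best_gain <- g; best_node <- v; best_add <- FALSE }
      }
    }
    if (best_node == 0L) break
    lv <- link[best_node]
    if (best_add) {
      w_in <- w_in + lv
      w_bound <- w_bound - lv + (sum(graph[best_node, ]) - lv)
      inside[best_node] <- TRUE
      size <- size + 1L
    } else {
      w_in <- w_in - lv
      w_bound <- w_bound - (sum(graph[best_node, ]) - lv) + lv
      inside[best_node] <- FALSE
      size <- size - 1L
    }
    current <- coh(w_in, w_bound, size)
  }
  which(inside)
}

merge_overlapping <- function(graph, clusters, penalty, threshold) {
  repeat {
    if (length(clusters) < 2) break
    merged <- FALSE
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        vi <- clusters[[i]]$members; vj <- clusters[[j]]$members
        ov <- length(intersect(vi, vj))^2 / (length(vi) * length(vj))
        if (ov > threshold) {
          u <- sort(union(vi, vj))
          clusters[[i]] <- list(members = u,
                                cohesion = cluster_cohesion(graph, u, penalty))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters
}

#' Boost similarity of co-clustered entities
#'
#' For each pair co-contained in at least one cluster the entry becomes
#' `(1 + C(V)) * sim[i, j]`, where `C(V)` is the cohesion of the most
#' cohesive shared cluster; any boosted value reaching 1 is replaced by
#' 0.99. Pairs in no common cluster, and the diagonal, are unchanged.
#'
#' @param sim A [similarity_matrix()].
#' @param clusters Output of [cluster_one()] over the same index space.
#' @return The enhanced similarity matrix.
#' @export
enhance_with_clusters <- function(sim, clusters) {
  m <- unclass(sim)
  boost <- matrix(0, nrow(m), ncol(m))
  for (cl in clusters) {
    idx <- cl$members
    boost[idx, idx] <- pmax(boost[idx, idx], cl$cohesion)
  }
  hit <- boost > 0
  diag(hit) <- FALSE
  out <- m
  out[hit] <- (1 + boost[hit]) * m[hit]
  out[hit & out >= 1] <- 0.99
  similarity_matrix(out, rownames(sim), kind = attr(sim, "kind"))
}

#' Semantic contribution values of a disease's ancestor closure
#'
#' In the disease's ancestor DAG, its own node(s) contribute 1 and every
#' ancestor `b` contributes `max(psi * D(b'))` over its children `b'`
#' inside the closure — contributions decay geometrically with distance.
#' The semantic value `DV` is the sum of contributions over the closure.
#'
#' @param dag A [disease_dag()].
#' @param disease A disease id present in `dag$leaf_map`.
#' @param psi Decay factor in (0, 1), default 0.5.
#' @return List with `D` (named numeric vector over the closure) and `DV`.
#' @export
semantic_values <- function(dag, disease, psi = 0.5) {
  stopifnot(psi > 0, psi < 1)
  own <- dag$leaf_map[[disease]]
  if (is.null(own))
    stop(sprintf("disease '%s' has no MeSH annotation; apply the zero-similarity fallback", disease))
  # ancestor closure
  closure <- own
  frontier <- own
  while (length(frontier)) {
    parents <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(parents, closure)
    closure <- c(closure, frontier)
  }
  # children within the closure (reverse of parent edges)
  children <- lapply(closure, function(b) {
    kids <- closure[vapply(closure, function(ch)
      b %in% dag$parents[[ch]], logical(1))]
    kids
  })
  names(children) <- closure
  D <- stats::setNames(rep(NA_real_, length(closure)), closure)
  D[own] <- 1
  # dynamic programming over a topological order (children before parents)
  remaining <- names(D)[is.na(D)]
  while (length(remaining)) {
    progressed <- FALSE
    for (b in remaining) {
      kids <- children[[b]]
      if (length(kids) && !anyNA(D[kids])) {
        D[b] <- max(psi * D[kids])
        progressed <- TRUE
      }
    }
    remaining <- names(D)[is.na(D)]
    if (!progressed && length(remaining))
      stop("disease DAG contains a cycle or a disconnected ancestor")
  }
  list(D = D, DV = sum(D))
}

#' Disease semantic similarity from MeSH ancestor DAGs
#'
#' `SV(i, j) = sum over shared closure nodes s of (D_i(s) + D_j(s)) /
#' (DV(i) + DV(j))`; diseases with identical annotations score 1, diseases
#' with no shared ancestor score 0. Diseases absent from the DAG fall back
#' to similarity 0 against every other disease (self-similarity 1), with a
#' warning.
#'
#' @inheritParams semantic_values
#' @param diseases Character vector of disease ids (matrix order).
#' @return A [similarity_matrix()] of kind `"disease_semantic"`.
#' @export
semantic_similarity <- function(dag, diseases, psi = 0.5) {
  known <- diseases %in% names(dag$leaf_map)
  if (any(!known))
    warning(sprintf("%d disease(s) missing from the MeSH tree; semantic similarity defaults to 0: %s",
                    sum(!known), paste(diseases[!known], collapse = ", ")))
  vals <- lapply(diseases[known], semantic_values, dag = dag, psi = psi)
  names(vals) <- diseases[known]
  n <- length(diseases)
  out <- diag(1, n)
  dimnames(out) <- list(diseases, diseases)
  ki <- which(known)
  if (length(ki) >= 2) {
    for (a in seq_along(ki)[-length(ki)]) {
      i <- ki[a]
      vi <- vals[[diseases[i]]]
      for (b in (a + 1):length(ki)) {
        j <- ki[b]
        vj <- vals[[diseases[j]]]
        shared <- intersect(names(vi$D), names(vj$D))
        sv <- if (length(shared))
          sum(vi$D[shared] + vj$D[shared]) / (vi$DV + vj$DV) else 0
        out[i, j] <- out[j, i] <- sv
      }
    }
  }
  similarity_matrix(out, diseases, kind = "disease_semantic")
}

#' Gaussian interaction profile kernel
#'
#' Kernel between binary association profiles: `exp(-theta * ||V(i) -
#' V(j)||^2)` with bandwidth `theta = theta_prime / mean(||V(u)||^2)`
#' normalized by the mean squared profile norm over the axis. Drug
#' profiles are columns of the association matrix, disease profiles rows.
#'
#' @param assoc An [association_matrix()].
#' @param axis `"drugs"` or `"diseases"`.
#' @param theta_prime Raw bandwidth, default 0.5.
#' @return A [similarity_matrix()] of kind `"gip_drug"` or `"gip_disease"`.
#' @export
gip_kernel <- function(assoc, axis = c("drugs", "diseases"),
                       theta_prime = 0.5) {
  axis <- match.arg(axis)
  stopifnot(theta_prime > 0)
  a <- unclass(assoc)
  storage.mode(a) <- "double"
  p <- if (axis == "drugs") t(a) else a   # profiles as rows
  norms2 <- rowSums(p^2)
  if (all(norms2 == 0))
    stop("all association profiles are zero; GIP bandwidth undefined")
  theta <- theta_prime / mean(norms2)
  d2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0
  k <- exp(-theta * d2)
  diag(k) <- 1
  similarity_matrix(k, rownames(p),
                    kind = if (axis == "drugs") "gip_drug" else "gip_disease")
}

#' Fuse GIP kernel with a structural/semantic fallback
#'
#' Entities with an all-zero association profile carry no GIP information,
#' so any pair involving one falls back to the structural (drugs) or
#' semantic (diseases) similarity; pairs where both profiles are non-zero
#' keep the GIP value. The diagonal is 1.
#'
#' @param gip GIP kernel [similarity_matrix()].
#' @param fallback Structural/semantic [similarity_matrix()] over the same
#'   entities.
#' @param assoc The [association_matrix()] the profiles come from.
#' @param axis `"drugs"` or `"diseases"`.
#' @return A [similarity_matrix()] of kind `"fused_drug"` or
#'   `"fused_disease"`.
#' @export
fuse_similarities <- function(gip, fallback, assoc,
                              axis = c("drugs", "diseases")) {
  axis <- match.arg(axis)
  stopifnot(nrow(gip) == nrow(fallback))
  a <- unclass(assoc)
  nz <- if (axis == "drugs") colSums(a) > 0 else rowSums(a) > 0
  both <- outer(nz, nz, "&")
  out <- unclass(fallback)
  out[both] <- unclass(gip)[both]
  diag(out) <- 1
  similarity_matrix(out, rownames(gip),
                    kind = if (axis == "drugs") "fused_drug" else "fused_disease")
}

#' Per-pair feature vectors
#'
#' The descriptor of a (drug, disease) pair is the drug's full row of the
#' fused drug similarity matrix concatenated with the disease's full row
#' of the fused disease similarity matrix, giving `n_drugs + n_diseases`
#' features (906 for a 593-drug/313-disease dataset).
#'
#' @param fused_drug,fused_disease Fused [similarity_matrix()] objects.
#' @param drug_index,disease_index Parallel integer vectors of 1-based
#'   indices, one element per pair.
#' @return Numeric matrix, one row per pair.
#' @export
pair_features <- function(fused_drug, fused_disease, drug_index,
                          disease_index) {
  stopifnot(length(drug_index) == length(disease_index))
  if (any(drug_index < 1 | drug_index > nrow(fused_drug)) ||
      any(disease_index < 1 | disease_index > nrow(fused_disease)))
    stop("pair index out of range")
  out <- cbind(unclass(fused_drug)[drug_index, , drop = FALSE],
               unclass(fused_disease)[disease_index, , drop = FALSE],
               deparse.level = 0)
  dimnames(out) <- NULL
  out
}

#' Full similarity profile computation
#'
#' Runs the whole similarity stage: logistic rescaling of the raw drug
#' structural similarity and of the DAG semantic disease similarity,
#' cohesive-cluster enhancement of each on its shared-association network,
#' GIP kernels on both axes, and GIP/fallback fusion.
#'
#' @param assoc An [association_matrix()].
#' @param drug_sim Raw drug structural [similarity_matrix()] (e.g. Tanimoto).
#' @param dag A [disease_dag()] covering the diseases (or `NULL` to use an
#'   identity semantic similarity).
#' @param c,f Logistic parameters, see [logistic_curve()].
#' @param psi Semantic decay, see [semantic_values()].
#' @param theta_prime GIP bandwidth, see [gip_kernel()].
#' @param penalty_per_node,min_cohesion,min_size,overlap_threshold
#'   Clustering controls, see [cluster_one()].
#' @param semantic_base Optional precomputed raw semantic similarity (skips
#'   the DAG computation; used to avoid recomputation across CV folds).
#' @return List with elements `drug` and `disease` (fused similarity
#'   matrices) plus the intermediate `drug_structural`, `disease_semantic`,
#'   `gip_drug`, `gip_disease` matrices.
#' @export
compute_similarity_profiles <- function(assoc, drug_sim, dag = NULL,
                                        c = -15, f = log(999), psi = 0.5,
                                        theta_prime = 0.5,
                                        penalty_per_node = 2,
                                        min_cohesion = 0.3, min_size = 3,
                                        overlap_threshold = 0.8,
                                        semantic_base = NULL) {
  stopifnot(identical(colnames(assoc), rownames(drug_sim)))
  de <- adjust_logistic(drug_sim, c = c, f = f)
  g_drug <- shared_association_graph(assoc, "drugs")
  de <- enhance_with_clusters(de, cluster_one(g_drug, penalty_per_node,
                                              min_cohesion, min_size,
                                              overlap_threshold))
  if (is.null(semantic_base)) {
    semantic_base <- if (is.null(dag)) {
      similarity_matrix(diag(1, nrow(assoc)), rownames(assoc),
                        kind = "disease_semantic")
    } else {
      semantic_similarity(dag, rownames(assoc), psi = psi)
    }
  }
  ds <- adjust_logistic(semantic_base, c = c, f = f)
  g_dis <- shared_association_graph(assoc, "diseases")
  ds <- enhance_with_clusters(ds, cluster_one(g_dis, penalty_per_node,
                                              min_cohesion, min_size,
                                              overlap_threshold))
  ge <- gip_kernel(assoc, "drugs", theta_prime)
  gd <- gip_kernel(assoc, "diseases", theta_prime)
  list(drug = fuse_similarities(ge, de, assoc, "drugs"),
       disease = fuse_similarities(gd, ds, assoc, "diseases"),
       drug_structural = de, disease_semantic = ds,
       gip_drug = ge, gip_disease = gd,
       semantic_base = semantic_base)
}
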