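# Similarity stage: logistic rescaling, shared-association network,
# cohesive clustering, DAG semantic similarity, GIP kernels, fusion.

test_that("logistic rescaling hits its anchor values and is increasing", {
  expect_equal(logistic_curve(0), 0.001)
  expect_equal(logistic_curve(1), 1 / (1 + 999 * exp(-15)), tolerance = 1e-12)
  expect_equal(logistic_curve(0.3), 1 / (1 + exp(-15 * 0.3 + log(999))),
               tolerance = 1e-12)
  expect_equal(round(logistic_curve(0.3), 5), 0.08266)
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(logistic_curve(grid)) > 0))

  s <- make_sim(4, seed = 2)
  adj <- adjust_logistic(s)
  expect_equal(unname(diag(adj)), rep(1, 4))
  expect_identical(unclass(adj), t(unclass(adj)))
})

test_that("shared-association weights count co-associated partners", {
  a <- make_assoc(matrix(c(1, 0, 1, 1), 2, 2))  # column-major: r1=(1,0), r2=(1,1)
  w <- shared_association_graph(a, "drugs")
  expect_equal(w[1, 2], 1)
  expect_equal(unname(diag(w)), c(0, 0))

  a2 <- make_random_assoc(6, 9, seed = 4)
  expect_equal(unname(shared_association_graph(a2, "diseases")),
               unname(shared_association_graph(make_assoc(t(unclass(a2))),
                                               "drugs")))
  zero_col <- make_assoc(cbind(matrix(1, 3, 2), 0))
  w3 <- shared_association_graph(zero_col, "drugs")
  expect_equal(unname(w3[3, ]), rep(0, 3))
})

test_that("cluster cohesion follows W_in / (W_in + W_bound + penalty)", {
  # path a-b (w=2), b-c (w=1)
  g <- matrix(0, 3, 3)
  g[1, 2] <- g[2, 1] <- 2
  g[2, 3] <- g[3, 2] <- 1
  expect_equal(cluster_cohesion(g, c(1, 2), penalty_per_node = 2), 2 / 7)
  # isolated pair, no boundary, no penalty
  g2 <- matrix(0, 4, 4); g2[1, 2] <- g2[2, 1] <- 5
  expect_equal(cluster_cohesion(g2, c(1, 2), penalty_per_node = 0), 1)
  # no internal or boundary edges at zero penalty: 0/0 convention
  expect_equal(cluster_cohesion(g2, c(3, 4), penalty_per_node = 0), 0)
  expect_error(cluster_cohesion(g2, c(1, 9)), "out of range")
})

test_that("cohesion stays in [0,1] and never increases with the penalty", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    w <- matrix(runif(n * n) * rbinom(n * n, 1, 0.5), n, n)
    w <- (w + t(w)) / 2; diag(w) <- 0
    members <- sample(n, sample(2:n, 1))
    c0 <- cluster_cohesion(w, members, 0)
    c1 <- cluster_cohesion(w, members, 1)
    c2 <- cluster_cohesion(w, members, 3)
    expect_true(all(c(c0, c1, c2) >= 0 & c(c0, c1, c2) <= 1))
    expect_true(c0 >= c1 && c1 >= c2)
  }
})

test_that("greedy clustering separates cohesive groups deterministically", {
  w <- two_triangle_graph()
  cl <- cluster_one(w, penalty_per_node = 2, min_cohesion = 0.3)
  expect_length(cl, 2)
  expect_setequal(lapply(cl, `[[`, "members"), list(1:3, 4:6))
  for (c_ in cl)
    expect_equal(c_$cohesion, cluster_cohesion(w, c_$members, 2))

  expect_length(cluster_one(matrix(0, 5, 5)), 0)

  tri <- two_triangle_graph()[1:3, 1:3]
  cl3 <- cluster_one(tri, penalty_per_node = 2, min_cohesion = 0.1,
                     overlap_threshold = 0.8)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$members, 1:3)
})

test_that("cluster co-membership boosts similarity with a 0.99 cap", {
  s <- similarity_matrix(matrix(c(1, 0.6, 0.6, 1), 2, 2), c("a", "b"))
  boosted <- enhance_with_clusters(s, list(list(members = 1:2,
                                                cohesion = 2 / 7)))
  expect_equal(boosted["a", "b"], (1 + 2 / 7) * 0.6, tolerance = 1e-12)

  s2 <- similarity_matrix(matrix(c(1, 0.9, 0.9, 1), 2, 2), c("a", "b"))
  capped <- enhance_with_clusters(s2, list(list(members = 1:2,
                                                cohesion = 0.5)))
  expect_equal(capped["a", "b"], 0.99)

  s3 <- make_sim(4, seed = 11)
  same <- enhance_with_clusters(s3, list(list(members = 1:2, cohesion = 0.4)))
  expect_equal(same[3, 4], s3[3, 4])       # pair in no cluster unchanged
  expect_equal(unname(diag(same)), rep(1, 4))
  # overlapping clusters: the most cohesive one wins
  s4 <- similarity_matrix(matrix(c(1, 0.5, 0.5, 1), 2, 2), c("a", "b"))
  multi <- enhance_with_clusters(s4, list(list(members = 1:2, cohesion = 0.1),
                                          list(members = 1:2, cohesion = 0.3)))
  expect_equal(multi["a", "b"], 1.3 * 0.5)
})

test_that("semantic contributions decay geometrically up the DAG", {
  dag <- toy_dag()
  sv <- semantic_values(dag, "B", psi = 0.5)     # leaf with one parent
  expect_equal(sv$DV, 1.5)
  expect_equal(unname(sv$D["C01.100"]), 1)
  expect_equal(unname(sv$D["C01"]), 0.5)

  expect_equal(semantic_values(dag, "A")$DV, 1)  # root-only disease

  chain <- disease_dag("X", "C01.100.200")
  expect_equal(semantic_values(chain, "X", psi = 0.5)$DV, 1.75)
  expect_error(semantic_values(dag, "nope"), "fallback")
})

test_that("disease semantic similarity matches its defining ratio", {
  dag <- toy_dag()
  sv <- semantic_similarity(dag, c("A", "B", "C"))
  # A (DV=1) vs child B (DV=1.5): shared node C01, D_A=1, D_B=0.5
  expect_equal(sv["A", "B"], 1.5 / 2.5)
  expect_equal(sv["A", "C"], 0)                  # disjoint branches
  expect_equal(unname(diag(sv)), rep(1, 3))

  dup <- disease_dag(c("P", "Q"), c("C03.5", "C03.5"))
  expect_equal(semantic_similarity(dup, c("P", "Q"))["P", "Q"], 1)

  expect_warning(sv2 <- semantic_similarity(dag, c("A", "unknown")),
                 "missing")
  expect_equal(sv2["A", "unknown"], 0)
  expect_equal(sv2["unknown", "unknown"], 1)
})

test_that("semantic similarity equals brute-force enumeration on small DAGs", {
  brute_D <- function(dag, disease, psi) {
    own <- dag$leaf_map[[disease]]
    # closure by repeated parent expansion
    closure <- own
    repeat {
      more <- setdiff(unique(unlist(dag$parents[closure])), closure)
      if (!length(more)) break
      closure <- c(closure, more)
    }
    D <- numeric(0)
    val <- function(b) {
      if (b %in% own) return(1)
      kids <- closure[vapply(closure, function(ch)
        b %in% dag$parents[[ch]], logical(1))]
      max(psi * vapply(kids, val, numeric(1)))
    }
    vapply(closure, val, numeric(1))
  }
  ds <- generate_dataset(n_drugs = 6, n_diseases = 8, n_groups = 2, seed = 21)
  ids <- ds$mesh$disease_id
  got <- semantic_similarity(ds$dag, ids, psi = 0.5)
  for (i in 1:4) for (j in (i + 1):5) {
    Di <- brute_D(ds$dag, ids[i], 0.5); Dj <- brute_D(ds$dag, ids[j], 0.5)
    shared <- intersect(names(Di), names(Dj))
    want <- if (length(shared))
      sum(Di[shared] + Dj[shared]) / (sum(Di) + sum(Dj)) else 0
    expect_equal(unname(got[ids[i], ids[j]]), want, tolerance = 1e-12)
  }
  expect_true(all(got >= 0 & got <= 1))
})

test_that("GIP kernel matches its closed form and a brute-force oracle", {
  a <- make_assoc(diag(2))
  g <- gip_kernel(a, "drugs", theta_prime = 0.5)
  expect_equal(g[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(unname(diag(g)), c(1, 1))

  dup <- make_assoc(cbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(gip_kernel(dup, "drugs")[1, 2], 1)

  a2 <- make_random_assoc(8, 6, seed = 13)
  for (axis in c("drugs", "diseases")) {
    got <- gip_kernel(a2, axis, theta_prime = 0.5)
    p <- if (axis == "drugs") t(unclass(a2)) else unclass(a2)
    theta <- 0.5 / mean(rowSums(p^2))
    n <- nrow(p)
    want <- matrix(1, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      want[i, j] <- exp(-theta * sum((p[i, ] - p[j, ])^2))
    diag(want) <- 1
    expect_equal(unclass(got)[, ], want, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  allzero <- matrix(0, 3, 3); allzero[1, 1] <- 1
  dimnames(allzero) <- list(paste0("d", 1:3), paste0("r", 1:3))
  a3 <- association_matrix(allzero)
  expect_s3_class(gip_kernel(a3, "drugs"), "similarity_matrix")
})

test_that("fusion keeps GIP for profiled pairs and falls back elsewhere", {
  m <- cbind(c(1, 0, 1), c(0, 1, 0), c(0, 0, 0))  # drug 3 has no profile
  a <- make_assoc(m)
  gip <- gip_kernel(a, "drugs")
  fb <- make_sim(3, ids = colnames(a), seed = 17)
  fused <- fuse_similarities(gip, fb, a, "drugs")
  expect_equal(fused[1, 2], gip[1, 2])
  expect_equal(fused[1, 3], fb[1, 3])
  expect_equal(fused[2, 3], fb[2, 3])
  expect_equal(unname(diag(fused)), rep(1, 3))
  # every cell comes from one of the two inputs
  ok <- unclass(fused) == unclass(gip) | unclass(fused) == unclass(fb) |
    row(fused) == col(fused)
  expect_true(all(ok))
  # identical inputs are a fixed point
  expect_equal(unclass(fuse_similarities(gip, gip, a, "drugs"))[, ],
               unclass(gip)[, ])
})

test_that("pair features concatenate the two similarity rows", {
  a <- make_random_assoc(5, 8, seed = 1)
  fd <- make_sim(8, ids = colnames(a), seed = 2)
  fdi <- make_sim(5, ids = rownames(a), seed = 3, kind = "disease_semantic")
  x <- pair_features(fd, fdi, c(2, 7), c(1, 5))
  expect_equal(dim(x), c(2, 13))
  expect_equal(x[1, 1:8], unname(unclass(fd)[2, ]))
  expect_equal(x[2, 9:13], unname(unclass(fdi)[5, ]))
  expect_error(pair_features(fd, fdi, 9, 1), "out of range")

  one_hot <- pair_features(similarity_matrix(diag(3), paste0("r", 1:3)),
                           similarity_matrix(diag(2), paste0("d", 1:2),
                                             kind = "disease_semantic"),
                           2, 1)
  expect_equal(as.numeric(one_hot), c(0, 1, 0, 1, 0))
})
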