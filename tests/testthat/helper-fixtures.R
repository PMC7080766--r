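# Shared fixture builders; everything is generated in code.

make_assoc <- function(m) {
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("d", seq_len(nrow(m))),
                        paste0("r", seq_len(ncol(m))))
  association_matrix(m)
}

# random symmetric unit-interval similarity with unit diagonal
make_sim <- function(n, ids = paste0("r", seq_len(n)), seed = 1,
                     kind = "drug_structural") {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  similarity_matrix(m, ids, kind = kind)
}

# random binary association matrix guaranteed non-degenerate
make_random_assoc <- function(n_dis, n_drug, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_dis * n_drug, 1, p), n_dis, n_drug)
    if (sum(m) > 0 && all(colSums(m) >= 0)) break
  }
  make_assoc(m)
}

# two disjoint triangles (edge weight 1) joined by a weak bridge
two_triangle_graph <- function(bridge = 0.1) {
  w <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    w[e[1], e[2]] <- w[e[2], e[1]] <- 1
  w[3, 4] <- w[4, 3] <- bridge
  w
}

# tiny disease DAG: root C01 with child C01.100, grandchild C01.100.200,
# and a disjoint root C02
toy_dag <- function() {
  disease_dag(c("A", "B", "C"),
              c("C01", "C01.100", "C02"))
}
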