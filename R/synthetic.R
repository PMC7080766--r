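# Synthetic block-model generator. Drugs and diseases share a latent
# grouping; associations are dense within matched groups and sparse
# elsewhere, drug structural similarity is high within groups, and
# disease tree numbers hang off one root branch per group so same-group
# diseases share deep ancestors. One latent grouping therefore drives
# all three similarity channels the pipeline consumes.

#' Generate a synthetic drug-disease dataset
#'
#' Drugs and diseases are assigned uniformly to `n_groups` groups.
#' Associations are Bernoulli(`within_group_assoc_prob`) for matched
#' groups and Bernoulli(`background_assoc_prob`) otherwise. Drug
#' structural similarity is 0.7 within groups and 0.2 across, plus
#' truncated Gaussian noise, symmetrized, clipped to \[0, 1\], with a
#' unit diagonal. Each group has a tree-number spine of depth
#' `dag_depth` under its own root; each disease's tree number extends a
#' random spine prefix (at least two segments deep) with its own leaf
#' segment, so same-group diseases always share a non-root ancestor.
#' If the association matrix comes out all-zero the generation is
#' retried with a derived seed, up to 10 times.
#'
#' @param n_drugs,n_diseases Entity counts (defaults 80 and 60).
#' @param n_groups Latent groups (default 4).
#' @param within_group_assoc_prob,background_assoc_prob Association
#'   probabilities (defaults 0.25 and 0.01).
#' @param sim_noise_sd Structural-similarity noise SD (default 0.05).
#' @param dag_depth Depth of each group's tree spine (default 3).
#' @param seed Integer seed; the whole triple is reproducible.
#' @return List with `assoc` ([association_matrix()]), `drug_sim`
#'   ([similarity_matrix()]), `mesh` (data frame `disease_id`,
#'   `tree_number`), `dag` ([disease_dag()]), and the group assignments
#'   `drug_group`, `disease_group`.
#' @export
generate_dataset <- function(n_drugs = 80, n_diseases = 60, n_groups = 4,
                             within_group_assoc_prob = 0.25,
                             background_assoc_prob = 0.01,
                             sim_noise_sd = 0.05, dag_depth = 3, seed = 1) {
  stopifnot(n_groups <= min(n_drugs, n_diseases), dag_depth >= 1,
            within_group_assoc_prob >= 0, within_group_assoc_prob <= 1,
            background_assoc_prob >= 0, background_assoc_prob <= 1)
  for (try in 0:10) {
    out <- with_seed(derive_seed(seed, try), generate_once(
      n_drugs, n_diseases, n_groups, within_group_assoc_prob,
      background_assoc_prob, sim_noise_sd, dag_depth))
    if (!is.null(out)) return(out)
  }
  stop("association matrix was all-zero after 10 regeneration attempts; raise the association probabilities")
}

generate_once <- function(n_drugs, n_diseases, n_groups, p_in, p_bg,
                          noise_sd, dag_depth) {
  drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
  disease_ids <- sprintf("disease%03d", seq_len(n_diseases))
  drug_group <- sample.int(n_groups, n_drugs, replace = TRUE)
  disease_group <- sample.int(n_groups, n_diseases, replace = TRUE)

  same <- outer(disease_group, drug_group, "==")
  p <- ifelse(same, p_in, p_bg)
  a <- matrix(rbinom(length(p), 1, p), n_diseases, n_drugs,
              dimnames = list(disease_ids, drug_ids))
  if (sum(a) == 0) return(NULL)

  base <- ifelse(outer(drug_group, drug_group, "=="), 0.7, 0.2)
  if (noise_sd > 0) {
    noise <- matrix(rnorm(n_drugs^2, 0, noise_sd), n_drugs, n_drugs)
    noise <- (noise + t(noise)) / 2
    base <- base + noise
  }
  base <- pmin(pmax(base, 0), 1)
  diag(base) <- 1
  drug_sim <- similarity_matrix(base, drug_ids, kind = "drug_structural")

  # per-group spine: G<g>, G<g>.S1, ..., G<g>.S<dag_depth>
  spines <- lapply(seq_len(n_groups), function(g)
    c(sprintf("G%02d", g),
      sprintf("G%02d.%s", g,
              vapply(seq_len(dag_depth), function(k)
                paste(sprintf("%03d", 100 + seq_len(k)), collapse = "."),
                character(1)))))
  depth_min <- 2L                      # share at least one non-root ancestor
  tree_numbers <- vapply(seq_len(n_diseases), function(i) {
    sp <- spines[[disease_group[i]]]
    depths <- depth_min:(dag_depth + 1L)
    k <- depths[sample.int(length(depths), 1)]
    sprintf("%s.%03d", sp[k], 500 + i)
  }, character(1))
  mesh <- data.frame(disease_id = disease_ids, tree_number = tree_numbers,
                     stringsAsFactors = FALSE)
  list(assoc = association_matrix(a),
       drug_sim = drug_sim,
       mesh = mesh,
       dag = disease_dag(mesh$disease_id, mesh$tree_number),
       drug_group = drug_group, disease_group = disease_group)
}

#' Write a synthetic dataset to disk
#'
#' Emits the three input files in the exact dialects the readers expect:
#' `association.tsv` (dense labeled TSV), `drug_similarity.tsv` (dense
#' labeled TSV) and `mesh_tree.tsv` (two-column TSV).
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("association.tsv", "drug_similarity.tsv",
                            "mesh_tree.tsv"))
  write_matrix_tsv(dataset$assoc, paths[1])
  write_matrix_tsv(dataset$drug_sim, paths[2])
  write.table(dataset$mesh, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
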