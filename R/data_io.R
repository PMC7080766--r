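# Input containers and TSV readers/writers.
#
# All matrices are plain base matrices carrying dimnames; orientation is
# fixed throughout the package as rows = diseases, columns = drugs for the
# association matrix. Files are label-addressed dense TSVs (first header
# cell empty) or two-column edge lists.

#' Construct and validate a binary association matrix
#'
#' @param values Binary matrix, rows = diseases, columns = drugs.
#' @param disease_ids,drug_ids Row/column labels; taken from `dimnames(values)`
#'   when omitted.
#' @return A validated integer matrix of class `"assoc_matrix"` with
#'   diseases as rows and drugs as columns.
#' @export
association_matrix <- function(values, disease_ids = rownames(values),
                               drug_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(disease_ids) || is.null(drug_ids))
    stop("association matrix needs disease (row) and drug (column) labels")
  storage.mode(values) <- "double"
  bad <- which(!(values %in% c(0, 1)) | !is.finite(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop(sprintf("non-binary association value at row '%s', column '%s'",
                 disease_ids[rc[1]], drug_ids[rc[2]]))
  }
  check_labels(disease_ids, "disease")
  check_labels(drug_ids, "drug")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("association matrix needs at least 2 diseases and 2 drugs")
  if (sum(values) == 0)
    stop("association matrix has no associations (all zeros)")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(disease_ids, drug_ids)
  class(values) <- c("assoc_matrix", class(values))
  values
}

check_labels <- function(ids, what) {
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("empty %s label", what))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate %s label: '%s'", what, ids[duplicated(ids)][1]))
  invisible(ids)
}

#' Construct and validate a similarity matrix
#'
#' Square symmetric unit-interval matrix over drugs or diseases. Values
#' outside \[0, 1\] by at most `1e-9` are clipped with a warning; symmetry is
#' enforced to within `1e-9`.
#'
#' @param values Square numeric matrix.
#' @param entity_ids Labels; taken from `rownames(values)` when omitted.
#' @param kind One of `"drug_structural"`, `"disease_semantic"`,
#'   `"gip_drug"`, `"gip_disease"`, `"fused_drug"`, `"fused_disease"`.
#' @return Numeric matrix of class `"similarity_matrix"` with a `kind`
#'   attribute.
#' @export
similarity_matrix <- function(values, entity_ids = rownames(values),
                              kind = c("drug_structural", "disease_semantic",
                                       "gip_drug", "gip_disease",
                                       "fused_drug", "fused_disease")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square")
  if (is.null(entity_ids)) stop("similarity matrix needs entity labels")
  check_labels(entity_ids, "entity")
  if (max(abs(values - t(values))) > 1e-9)
    stop("similarity matrix is asymmetric beyond tolerance 1e-9")
  lo <- min(values); hi <- max(values)
  if (lo < -1e-9 || hi > 1 + 1e-9)
    stop(sprintf("similarity values outside [0,1]: range [%g, %g]", lo, hi))
  if (lo < 0 || hi > 1) {
    warning("similarity values marginally outside [0,1]; clipping")
    values <- pmin(pmax(values, 0), 1)
  }
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(values, kind = kind,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Read an association matrix from TSV
#'
#' Dense form: header row of drug ids, first column of disease ids, cells in
#' `{0,1}`. Edge-list form: two columns `disease_id`, `drug_id`; duplicate
#' rows collapse to a single association, and the matrix spans the distinct
#' labels in order of first appearance.
#'
#' @param path Path to the TSV file.
#' @param format `"dense_tsv"` or `"edge_list_tsv"`.
#' @return An [association_matrix()].
#' @export
read_association_matrix <- function(path,
                                    format = c("dense_tsv", "edge_list_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense_tsv") {
    raw <- read.delim(path, check.names = FALSE, row.names = 1,
                      colClasses = "character")
    m <- as.matrix(raw)
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                   dimnames = dimnames(m)))
    bad <- which(is.na(num) | !(num %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(num))
      stop(sprintf("non-binary cell '%s' at row '%s', column '%s'",
                   m[bad[1]], rownames(m)[rc[1]], colnames(m)[rc[2]]))
    }
    association_matrix(num)
  } else {
    el <- read.delim(path, colClasses = "character")
    if (ncol(el) < 2) stop("edge list needs columns disease_id, drug_id")
    diseases <- unique(el[[1]]); drugs <- unique(el[[2]])
    m <- matrix(0, length(diseases), length(drugs),
                dimnames = list(diseases, drugs))
    m[cbind(match(el[[1]], diseases), match(el[[2]], drugs))] <- 1
    association_matrix(m)
  }
}

#' Read a similarity matrix from labeled dense TSV
#'
#' Requires a square matrix with matching row/column labels; matrices
#' asymmetric by at most `1e-6` are symmetrized as `(M + t(M)) / 2`.
#'
#' @inheritParams read_association_matrix
#' @param kind Passed to [similarity_matrix()].
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, kind = "drug_structural") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric similarity value in ", path)
  if (nrow(m) != ncol(m))
    stop(sprintf("similarity matrix must be square; got %d x %d",
                 nrow(m), ncol(m)))
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop(sprintf("similarity matrix asymmetric beyond 1e-6 (max deviation %g)",
                 asym))
  m <- (m + t(m)) / 2
  similarity_matrix(m, kind = kind)
}

#' Write a labeled matrix as dense TSV
#'
#' Tab-delimited UTF-8 with an empty first header cell; the canonical
#' on-disk format for association and similarity matrices. Round-trips
#' bit-exactly through the matching reader.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Parse MeSH tree numbers into a disease ancestor DAG
#'
#' Each tree number (e.g. `"C04.588.945"`) contributes its chain of dot
#' prefixes as nodes (`C04`, `C04.588`, `C04.588.945`) with parent edges
#' from each extension to its prefix; the disease maps to its full
#' tree-number node(s).
#'
#' @param path TSV with columns `disease_id`, `tree_number` (a disease may
#'   have several rows).
#' @return A list of class `"disease_dag"` with elements `nodes` (character),
#'   `parents` (named list: child node -> character vector of parents) and
#'   `leaf_map` (named list: disease_id -> its annotated nodes).
#' @export
read_mesh_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, colClasses = "character")
  if (ncol(tab) < 2) stop("MeSH tree file needs columns disease_id, tree_number")
  disease_dag(tab[[1]], tab[[2]])
}

#' @rdname read_mesh_tree
#' @param disease_ids,tree_numbers Parallel character vectors (one row each).
#' @export
disease_dag <- function(disease_ids, tree_numbers) {
  stopifnot(length(disease_ids) == length(tree_numbers))
  nodes <- character(0)
  parents <- list()
  leaf_map <- list()
  for (i in seq_along(tree_numbers)) {
    tn <- tree_numbers[i]
    segs <- strsplit(tn, ".", fixed = TRUE)[[1]]
    if (length(segs) == 0 || any(!nzchar(segs)))
      stop(sprintf("malformed tree number '%s' for disease '%s'",
                   tn, disease_ids[i]))
    chain <- vapply(seq_along(segs),
                    function(k) paste(segs[seq_len(k)], collapse = "."),
                    character(1))
    nodes <- union(nodes, chain)
    if (length(chain) > 1)
      for (k in 2:length(chain))
        parents[[chain[k]]] <- union(parents[[chain[k]]], chain[k - 1])
    d <- disease_ids[i]
    leaf_map[[d]] <- union(leaf_map[[d]], chain[length(chain)])
  }
  structure(list(nodes = nodes, parents = parents, leaf_map = leaf_map),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease DAG: %d nodes, %d annotated diseases\n",
              length(x$nodes), length(x$leaf_map)))
  invisible(x)
}

#' Write ranked predictions as TSV
#'
#' @param ranking Data frame with columns `drug_id`, `disease_id`, `score`.
#' @param path Output path.
#' @export
write_predictions <- function(ranking, path) {
  stopifnot(all(c("drug_id", "disease_id", "score") %in% names(ranking)))
  ranking <- ranking[order(-ranking$score, ranking$drug_id), ]
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
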