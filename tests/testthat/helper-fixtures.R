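# Small in-code fixtures shared across test files.

# A toy study: 3 probes x (3 normal + 2 primary + 2 comparator) samples.
toy_study <- function(study_id = "s1") {
  vals <- rbind(
    p1 = c(5, 6, 7, 6, 8, 6.5, 7.5),
    p2 = c(1, 1, 1, 3, 3, 1, 1),
    p3 = c(2, 2, 2, 2, 2, 4, 4))
  colnames(vals) <- paste0(study_id, "_", 1:7)
  expression_study(study_id, vals,
                   c("normal", "normal", "normal",
                     "disease_primary", "disease_primary",
                     "disease_comparator", "disease_comparator"))
}

# A gene-level fold-change matrix built directly.
make_fcm <- function(values, study_id = "s", condition = "disease_primary",
                     level = "gene") {
  structure(list(study_id = study_id, values = values,
                 condition = condition, level = level),
            class = "fold_change_matrix")
}

# A dep_clusters table built directly (for the selection/classification
# rules, which only read the columns).
make_clusters <- function(cluster, direction, members, samples,
                          sample_info = NULL) {
  out <- data.frame(cluster = cluster, direction = direction,
                    n_members = lengths(members),
                    n_samples = lengths(samples),
                    stringsAsFactors = FALSE)
  out$members <- members
  out$samples <- samples
  out$significant <- rep(NA, nrow(out))
  out$class_label <- rep(NA_character_, nrow(out))
  attr(out, "sample_info") <- sample_info
  class(out) <- c("dep_clusters", "data.frame")
  out
}

make_thresholds <- function(gene = 0, sample = 0) {
  structure(list(gene_count_threshold = gene,
                 sample_count_threshold = sample,
                 basis_cutoff = NA_real_, activation_cutoff = NA_real_,
                 percentile = 95, n_permutations = 0L),
            class = "perm_thresholds")
}

# Distance-<=2 hit count by plain adjacency algebra, independent of igraph
# traversal: reachable = (A + A^2) > 0, diagonal excluded.
brute_force_n12_hits <- function(g, regulator, gene_set) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  R <- (A + A %*% A) > 0
  diag(R) <- FALSE
  nb <- colnames(R)[R[regulator, ]]
  length(intersect(nb, gene_set))
}

# Tiny edge-list file writers for the loaders.
write_edges_tsv <- function(edges, path) {
  writeLines(vapply(edges, paste, "", collapse = "\t"), path)
  path
}
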