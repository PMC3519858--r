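# Differential-expression-pattern (DEP) discovery: element-permutation
# significance thresholds for the NMF clusters, per-cluster membership and
# sample association, shared-vs-dominant classification, and the core
# disease-dominant gene set.

#' Permutation-derived significance thresholds for DEP clusters
#'
#' The elements of the combined fold-change matrix are globally permuted,
#' the permuted matrix re-folded and re-factorized, and within each
#' permutation the `percentile`-th percentile of the basis values and of the
#' activation values serve as cutoffs. Per permutation three per-cluster
#' maxima are recorded: the count of features above the basis cutoff, the
#' count of samples above the activation cutoff, and the count of
#' adjusted-p members per (cluster, direction) — the same statistic used
#' for the observed clusters, so the comparison is calibrated. The
#' gene/sample thresholds are the `percentile`-th percentile of those
#' maxima across permutations (conservative); the exported
#' basis/activation cutoffs are the medians of the per-permutation
#' cutoffs.
#'
#' @param combined a `combined_fc_matrix`.
#' @param n_clusters NMF rank (default 30, the full-scale study operating point).
#' @param n_permutations number of element permutations (>= 1).
#' @param percentile cutoff percentile in (0, 100), default 95.
#' @param seed integer seed.
#' @param max_iter,n_restarts,init NMF settings for the null factorizations
#'   (defaults lighter than for the observed matrix: a permuted matrix has
#'   no structure for restarts to disambiguate).
#' @param alpha membership level used for the null member counts; use the
#'   same value as for the observed clusters.
#' @return object of class `perm_thresholds`: `gene_count_threshold` (on
#'   member counts), `sample_count_threshold`, `basis_cutoff`,
#'   `activation_cutoff`, `cutoff_gene_count_threshold` (diagnostic: the
#'   basis-cutoff count statistic), `percentile`, `n_permutations`, plus
#'   the per-permutation maxima vectors.
#' @export
permutation_significance_thresholds <- function(combined, n_clusters,
                                                n_permutations = 20L,
                                                percentile = 95,
                                                seed = 1L,
                                                max_iter = 250L,
                                                n_restarts = 1L,
                                                init = "nnsvd",
                                                alpha = 0.05) {
  stopifnot(inherits(combined, "combined_fc_matrix"))
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)", call. = FALSE)
  vals <- combined$values
  if (stats::sd(vals) == 0)
    warning("combined matrix is constant; permutation cutoffs are degenerate",
            call. = FALSE)
  if (n_permutations < 20L)
    warning("fewer than 20 permutations gives a coarse percentile estimate",
            call. = FALSE)
  p <- percentile / 100
  gmax <- mmax <- smax <- bcut <- acut <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- vals
    perm[] <- with_seed(derive_seed(seed, b), sample(as.vector(vals)))
    V <- fold_signed_matrix(perm)
    fit <- suppressWarnings(factorize_nmf(
      V, n_clusters, seed = derive_seed(seed, 100000L + b),
      max_iter = max_iter, n_restarts = n_restarts, init = init))
    bcut[b] <- stats::quantile(fit$basis, p, names = FALSE)
    acut[b] <- stats::quantile(fit$activation, p, names = FALSE)
    gmax[b] <- max(colSums(fit$basis > bcut[b]))
    mem <- compute_membership_pvalues(fit, alpha = alpha)
    counts <- integer(n_clusters)
    if (nrow(mem)) {
      tab <- table(factor(mem$cluster, levels = seq_len(n_clusters)),
                   mem$direction)
      counts <- apply(tab, 1L, max)
    }
    # joint per-cluster statistic: the best null DEP's member count AND the
    # sample count of that same cluster ("N genes in M samples by chance")
    assoc <- associated_sample_counts(fit$activation)
    best <- which.max(counts)
    mmax[b] <- counts[best]
    smax[b] <- assoc[best]
  }
  structure(list(
    gene_count_threshold = stats::quantile(mmax, p, names = FALSE),
    sample_count_threshold = stats::quantile(smax, p, names = FALSE),
    basis_cutoff = stats::median(bcut),
    activation_cutoff = stats::median(acut),
    cutoff_gene_count_threshold = stats::quantile(gmax, p, names = FALSE),
    percentile = percentile, n_permutations = n_permutations,
    member_count_max = mmax, gene_count_max = gmax,
    sample_count_max = smax, seed = seed),
    class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf(
    "<perm_thresholds> %d permutations, %gth percentile\n  gene count > %.1f, sample count > %.1f; basis cutoff %.4g, activation cutoff %.4g\n",
    x$n_permutations, x$percentile, x$gene_count_threshold,
    x$sample_count_threshold, x$basis_cutoff, x$activation_cutoff))
  invisible(x)
}

#' Sample association by column-relative activation
#'
#' A sample is associated with every cluster whose activation reaches at
#' least `frac` of that sample's maximal activation — the soft version of
#' the standard assign-to-maximal-cluster rule, robust to the differing
#' magnitudes of concentrated and broadly active clusters.
#'
#' @param H activation matrix (clusters x samples).
#' @param frac fraction of the per-sample maximum (default 0.5).
#' @return logical clusters x samples matrix of associations.
#' @export
associated_samples_matrix <- function(H, frac = 0.5) {
  cmax <- apply(H, 2L, max)
  ok <- sweep(H, 2L, pmax(cmax, .Machine$double.xmin) * frac, ">=") &
    cmax[col(H)] > 0
  dimnames(ok) <- dimnames(H)
  ok
}

associated_sample_counts <- function(H, frac = 0.5) {
  rowSums(associated_samples_matrix(H, frac))
}

#' Assemble DEP cluster entries from a factorization
#'
#' One entry per (cluster, direction) with at least one member: members come
#' from [compute_membership_pvalues()] (adjusted p < `alpha`); a cluster's
#' associated samples come from [associated_samples_matrix()]. A cluster
#' whose members span both directions yields two entries sharing the same
#' associated samples, so a cluster can appear in both an up- and a
#' down-regulated group.
#'
#' @param fit an `nmf_fit` on the folded combined matrix.
#' @param thresholds a `perm_thresholds`.
#' @param samples the `samples` data.frame of the `combined_fc_matrix`.
#' @param alpha membership significance level.
#' @param assoc_frac fraction of the per-sample maximal activation defining
#'   sample association.
#' @return a `dep_clusters` data.frame: `cluster`, `direction`,
#'   `n_members`, `n_samples`, with list columns `members` (gene ids) and
#'   `samples` (associated sample column ids); plus `significant` and
#'   `class_label` placeholders filled by the selection/classification
#'   steps.
#' @export
dep_clusters <- function(fit, thresholds, samples, alpha = 0.05,
                         assoc_frac = 0.5) {
  stopifnot(inherits(fit, "nmf_fit"), inherits(thresholds, "perm_thresholds"))
  membership <- compute_membership_pvalues(fit, alpha = alpha)
  assoc_m <- associated_samples_matrix(fit$activation, frac = assoc_frac)
  rows <- list()
  for (j in seq_len(fit$n_clusters)) {
    assoc <- colnames(fit$activation)[assoc_m[j, ]]
    mem_j <- membership[membership$cluster == j, , drop = FALSE]
    for (dir in c("up", "down")) {
      genes <- unique(mem_j$gene[mem_j$direction == dir])
      if (!length(genes)) next
      rows[[length(rows) + 1L]] <- list(
        cluster = j, direction = dir, n_members = length(genes),
        n_samples = length(assoc), members = genes, samples = assoc)
    }
  }
  out <- data.frame(
    cluster = vapply(rows, `[[`, 1L, "cluster"),
    direction = vapply(rows, `[[`, "", "direction"),
    n_members = vapply(rows, `[[`, 1L, "n_members"),
    n_samples = vapply(rows, `[[`, 1L, "n_samples"),
    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  out$samples <- lapply(rows, `[[`, "samples")
  out$significant <- rep(NA, nrow(out))
  out$class_label <- rep(NA_character_, nrow(out))
  attr(out, "sample_info") <- samples
  attr(out, "membership") <- membership
  class(out) <- c("dep_clusters", "data.frame")
  out
}

#' Select significant DEP clusters
#'
#' An entry is significant when its member count exceeds the permutation
#' gene-count threshold AND its associated-sample count exceeds the
#' sample-count threshold (strict inequalities, mirroring the
#' "more than N genes in more than M samples" rule).
#'
#' @param clusters a `dep_clusters` data.frame.
#' @param thresholds a `perm_thresholds`.
#' @return `clusters` with the `significant` column filled.
#' @export
select_significant_dep_clusters <- function(clusters, thresholds) {
  stopifnot(inherits(clusters, "dep_clusters"),
            inherits(thresholds, "perm_thresholds"))
  clusters$significant <- clusters$n_members > thresholds$gene_count_threshold &
    clusters$n_samples > thresholds$sample_count_threshold
  clusters
}

#' Classify DEP clusters as shared or disease-dominant
#'
#' Among an entry's associated samples, `f_primary` and `f_comparator` are
#' the fractions drawn from the primary-disease and comparator arms. An
#' entry is `dominant` when the comparator fraction falls below
#' `dominant_max_comparator` and its primary samples span at least
#' `min_primary_studies` studies; `shared` when both fractions are at least
#' `shared_min_fraction`; otherwise `unclassified` (as is any entry with no
#' associated samples).
#'
#' @param clusters a `dep_clusters` data.frame.
#' @param sample_info optional sample sheet (data.frame with `sample_id`,
#'   `study_id`, `condition`); defaults to the one attached by
#'   [dep_clusters()]. Sample column ids are matched as
#'   `<study_id>.<sample_id>`.
#' @param dominant_max_comparator,shared_min_fraction,min_primary_studies
#'   classification thresholds (defaults 0.2, 0.2, 2).
#' @return `clusters` with `class_label` filled and columns `f_primary`,
#'   `f_comparator`, `n_primary_studies` added.
#' @export
classify_dep_clusters <- function(clusters, sample_info = NULL,
                                  dominant_max_comparator = 0.2,
                                  shared_min_fraction = 0.2,
                                  min_primary_studies = 2L) {
  stopifnot(inherits(clusters, "dep_clusters"))
  info <- sample_info %||% attr(clusters, "sample_info")
  if (is.null(info)) stop("sample_info required", call. = FALSE)
  key <- paste(info$study_id, info$sample_id, sep = ".")
  fp <- fc <- numeric(nrow(clusters))
  nps <- integer(nrow(clusters))
  label <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    s <- clusters$samples[[i]]
    if (!length(s)) { label[i] <- "unclassified"; next }
    idx <- match(s, key)
    cond <- info$condition[idx]
    fp[i] <- mean(cond == "disease_primary")
    fc[i] <- mean(cond == "disease_comparator")
    nps[i] <- length(unique(info$study_id[idx][cond == "disease_primary"]))
    label[i] <-
      if (fc[i] < dominant_max_comparator && nps[i] >= min_primary_studies)
        "dominant"
      else if (fp[i] >= shared_min_fraction && fc[i] >= shared_min_fraction)
        "shared"
      else "unclassified"
  }
  clusters$f_primary <- fp
  clusters$f_comparator <- fc
  clusters$n_primary_studies <- nps
  clusters$class_label <- label
  clusters
}

#' Core disease-dominant up-regulated genes
#'
#' The union of the member genes of all significant, dominant, up-direction
#' cluster entries. Soft-clustering duplicates (a gene belonging to several
#' such clusters) collapse to a set, so the per-cluster membership sum can
#' exceed the core-set size.
#'
#' @param clusters a classified `dep_clusters` data.frame.
#' @param direction which direction to pool (default `"up"`).
#' @param class_label which class to pool (default `"dominant"`).
#' @return sorted character vector of gene ids (possibly empty).
#' @export
derive_core_genes <- function(clusters, direction = "up",
                              class_label = "dominant") {
  stopifnot(inherits(clusters, "dep_clusters"))
  keep <- clusters$direction == direction &
    clusters$class_label %in% class_label &
    clusters$significant %in% TRUE
  sort(unique(as.character(unlist(clusters$members[keep]))))
}

#' DEP discovery in one call
#'
#' Folds the combined matrix, derives permutation thresholds, factorizes the
#' observed matrix, assembles cluster entries, applies the significance
#' selection and the shared/dominant classification, and extracts the core
#' gene set.
#'
#' @param combined a `combined_fc_matrix`.
#' @param n_clusters NMF rank (default 30).
#' @param alpha membership significance level.
#' @param n_permutations element permutations for the null thresholds.
#' @param percentile cutoff percentile.
#' @param seed integer seed governing every stochastic step.
#' @param n_restarts restarts for the observed-matrix factorization
#'   (random init only).
#' @param max_iter iteration cap for the observed-matrix factorization.
#' @param init NMF initialization, see [factorize_nmf()].
#' @param ... passed to [classify_dep_clusters()].
#' @return object of class `dep_result`: `fit` (`nmf_fit`), `thresholds`
#'   (`perm_thresholds`), `clusters` (`dep_clusters`), `core_genes`,
#'   `alpha`, `seed`.
#' @export
discover_deps <- function(combined, n_clusters = 30L, alpha = 0.05,
                          n_permutations = 20L, percentile = 95,
                          seed = 1L, n_restarts = 5L, max_iter = 500L,
                          init = "nnsvd", ...) {
  stopifnot(inherits(combined, "combined_fc_matrix"))
  thresholds <- permutation_significance_thresholds(
    combined, n_clusters, n_permutations = n_permutations,
    percentile = percentile, seed = derive_seed(seed, 1L), init = init,
    alpha = alpha)
  V <- fold_signed_matrix(combined)
  fit <- factorize_nmf(V, n_clusters, seed = derive_seed(seed, 2L),
                       max_iter = max_iter, n_restarts = n_restarts,
                       init = init)
  clusters <- dep_clusters(fit, thresholds, combined$samples, alpha = alpha)
  clusters <- select_significant_dep_clusters(clusters, thresholds)
  clusters <- classify_dep_clusters(clusters, combined$samples, ...)
  structure(list(fit = fit, thresholds = thresholds, clusters = clusters,
                 core_genes = derive_core_genes(clusters),
                 alpha = alpha, seed = seed),
            class = "dep_result")
}

#' @export
print.dep_result <- function(x, ...) {
  sig <- x$clusters[x$clusters$significant %in% TRUE, ]
  cat(sprintf(
    "<dep_result> k = %d: %d cluster entries, %d significant (%s)\n  %d core dominant-up genes\n",
    x$fit$n_clusters, nrow(x$clusters), nrow(sig),
    paste(sprintf("%d%s/%s", sig$cluster, substr(sig$direction, 1, 1),
                  substr(sig$class_label, 1, 4)), collapse = ", "),
    length(x$core_genes)))
  invisible(x)
}
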