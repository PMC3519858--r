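# Preprocessing: per-study log2 fold-change matrices relative to the median
# of the normal samples, probe-to-gene collapse, cross-study quantile
# normalization of the flattened matrices, and combination into one
# gene x sample matrix.

#' Construct an expression study
#'
#' Bundles one study's log2-intensity matrix with its per-sample condition
#' labels. Intensities must be finite; probe ids must be unique.
#'
#' @param study_id study identifier.
#' @param values probe x sample numeric matrix of log2 intensities, with
#'   probe ids as rownames and sample ids as colnames.
#' @param condition character vector, one label per sample, from
#'   `normal`, `disease_primary`, `disease_comparator`, `treated`, `control`.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(study_id, values, condition) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs probe rownames and sample colnames", call. = FALSE)
  stopifnot_finite(values, "log2 intensities")
  if (anyDuplicated(rownames(values)))
    stop("probe ids must be unique within a study", call. = FALSE)
  if (length(condition) != ncol(values))
    stop("one condition label per sample required", call. = FALSE)
  bad <- setdiff(unique(condition), condition_levels())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(study_id = as.character(study_id), values = values,
                 condition = as.character(condition)),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d probes x %d samples (%s)\n",
              x$study_id, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Compute log2 fold-changes against the normal-sample median
#'
#' For every probe, subtracts the median log2 intensity over the study's
#' normal samples from each sample of the target condition, producing one
#' fold-change matrix per disease arm (run once per arm).
#'
#' @param study an [expression_study()].
#' @param target_condition condition whose samples form the columns
#'   (e.g. `"disease_primary"`).
#' @return a `fold_change_matrix`: list with `study_id`, `values`
#'   (probe/gene x sample log2 fold-changes), `condition`, and `level`
#'   (`"probe"` or `"gene"`).
#' @export
compute_fold_changes <- function(study, target_condition) {
  stopifnot(inherits(study, "expression_study"))
  normal <- study$condition == "normal"
  if (!any(normal))
    stop("study '", study$study_id,
         "' has no normal samples; fold-changes need a normal reference",
         call. = FALSE)
  target <- study$condition == target_condition
  if (!any(target))
    stop("no samples with condition '", target_condition, "' in study '",
         study$study_id, "'", call. = FALSE)
  ref <- apply(study$values[, normal, drop = FALSE], 1L, stats::median)
  fc <- study$values[, target, drop = FALSE] - ref
  structure(list(study_id = study$study_id, values = fc,
                 condition = target_condition, level = "probe"),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf("<fold_change_matrix> %s/%s: %d %ss x %d samples\n",
              x$study_id, x$condition, nrow(x$values), x$level,
              ncol(x$values)))
  invisible(x)
}

#' Collapse probes to genes by the strongest probe
#'
#' When several probes map to one gene, the representative row is the probe
#' with the largest absolute log2 fold-change anywhere across its samples
#' (signed maxima would discard strong down-regulation); ties break to the
#' lexicographically smallest probe id. Unmapped probes are dropped and
#' counted.
#'
#' @param fc a probe-level `fold_change_matrix`.
#' @param probe_to_gene named character vector, `map[probe_id] == gene_id`.
#' @return a gene-level `fold_change_matrix`, rows ordered by gene id, with
#'   attribute `dropped_probes` (count of unmapped probes).
#' @export
collapse_probes_to_genes <- function(fc, probe_to_gene) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  if (fc$level != "probe")
    stop("`fc` is already at gene level", call. = FALSE)
  if (!length(probe_to_gene)) stop("empty probe map", call. = FALSE)
  probes <- rownames(fc$values)
  mapped <- probes %in% names(probe_to_gene)
  if (!any(mapped))
    stop("no probe of this matrix is covered by the map", call. = FALSE)
  vals <- fc$values[mapped, , drop = FALSE]
  genes <- unname(probe_to_gene[rownames(vals)])
  # per probe, strength = max_j |fold-change|; representative = strongest
  strength <- apply(abs(vals), 1L, max)
  ord <- order(genes, -strength, rownames(vals))
  first <- !duplicated(genes[ord])
  keep <- ord[first]
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  structure(list(study_id = fc$study_id, values = out,
                 condition = fc$condition, level = "gene"),
            class = "fold_change_matrix",
            dropped_probes = sum(!mapped))
}

# Quantile-normalize a list of numeric vectors as one group. Unequal lengths
# are handled by linearly interpolating each sorted vector onto a common grid
# of max-length quantile probabilities before averaging; with equal lengths
# this is exactly the mean-of-order-statistics reference.
quantile_normalize_vectors <- function(vectors) {
  lens <- lengths(vectors)
  if (any(lens < 2L))
    stop("each matrix must contribute at least 2 entries", call. = FALSE)
  L <- max(lens)
  grid <- seq(0, 1, length.out = L)
  interp <- vapply(vectors, function(v) {
    s <- sort(v)
    if (length(s) == L) s
    else stats::approx(seq(0, 1, length.out = length(s)), s, xout = grid)$y
  }, numeric(L))
  ref <- rowMeans(interp)
  lapply(vectors, function(v) {
    r <- rank(v, ties.method = "average")
    p <- (r - 1) / (length(v) - 1)
    stats::approx(grid, ref, xout = p)$y
  })
}

#' Cross-study quantile normalization of fold-change matrices
#'
#' Each matrix is flattened to a single vector; the vectors are quantile-
#' normalized as a group (so no study dominates through larger fold-changes)
#' and reshaped back. Unequal lengths are mapped onto a common quantile grid
#' by linear interpolation.
#'
#' @param matrices list of `fold_change_matrix` objects (>= 2).
#' @return list of `fold_change_matrix` objects with normalized values, same
#'   shapes and dimnames.
#' @export
cross_study_quantile_normalize <- function(matrices) {
  if (length(matrices) < 2L)
    stop("need >= 2 matrices to cross-normalize", call. = FALSE)
  lapply(matrices, function(m) stopifnot(inherits(m, "fold_change_matrix")))
  vectors <- lapply(matrices, function(m) as.vector(m$values))
  normed <- quantile_normalize_vectors(vectors)
  Map(function(m, v) {
    m$values[] <- v
    m
  }, matrices, normed)
}

#' Combine gene-level fold-change matrices across studies
#'
#' Column-wise concatenation over the gene-id match. With the default
#' `match = "intersection"` only genes present in every matrix are kept;
#' `match = "union"` keeps all genes and fills absences with `NA` (flagged in
#' the `n_missing` attribute) — note the factorization stage requires a
#' complete matrix.
#'
#' @param matrices list of gene-level `fold_change_matrix` objects.
#' @param match `"intersection"` (default) or `"union"`.
#' @return a `combined_fc_matrix`: list with `values` (gene x sample),
#'   `samples` (data.frame study_id, sample_id, condition), `gene_ids`.
#' @export
combine_matrices <- function(matrices, match = c("intersection", "union")) {
  match <- match.arg(match)
  lapply(matrices, function(m) {
    stopifnot(inherits(m, "fold_change_matrix"))
    if (m$level != "gene")
      stop("combine_matrices expects gene-level matrices", call. = FALSE)
  })
  key <- unlist(lapply(matrices, function(m)
    paste(m$study_id, colnames(m$values), sep = "\r")))
  if (anyDuplicated(key))
    stop("duplicate (study, sample) pair across matrices", call. = FALSE)
  gene_sets <- lapply(matrices, function(m) rownames(m$values))
  genes <- if (match == "intersection") Reduce(intersect, gene_sets)
           else Reduce(union, gene_sets)
  genes <- sort(genes)
  if (!length(genes)) stop("no genes left after matching", call. = FALSE)
  blocks <- lapply(matrices, function(m) {
    out <- matrix(NA_real_, length(genes), ncol(m$values),
                  dimnames = list(genes, colnames(m$values)))
    have <- intersect(genes, rownames(m$values))
    out[have, ] <- m$values[have, , drop = FALSE]
    out
  })
  values <- do.call(cbind, blocks)
  samples <- do.call(rbind, lapply(matrices, function(m)
    data.frame(study_id = m$study_id, sample_id = colnames(m$values),
               condition = m$condition, stringsAsFactors = FALSE)))
  colnames(values) <- paste(samples$study_id, samples$sample_id, sep = ".")
  structure(list(values = values, samples = samples, gene_ids = genes),
            class = "combined_fc_matrix", n_missing = sum(is.na(values)))
}

#' @export
print.combined_fc_matrix <- function(x, ...) {
  cat(sprintf(
    "<combined_fc_matrix> %d genes x %d samples from %d studies\n",
    nrow(x$values), ncol(x$values), length(unique(x$samples$study_id))))
  invisible(x)
}

#' Full preprocessing for a set of studies
#'
#' Runs, in order: per-arm fold-change computation against the normal
#' medians (one matrix per study per disease arm present), probe collapse,
#' cross-study quantile normalization of the flattened matrices, and
#' combination by gene id.
#'
#' @param studies list of [expression_study()] objects.
#' @param probe_to_gene named probe-to-gene character vector.
#' @param arms disease arms to extract (default primary + comparator).
#' @param match gene-matching policy, see [combine_matrices()].
#' @return a `combined_fc_matrix`.
#' @export
preprocess_studies <- function(studies, probe_to_gene,
                               arms = c("disease_primary",
                                        "disease_comparator"),
                               match = "intersection") {
  mats <- list()
  for (st in studies) {
    for (arm in intersect(arms, unique(st$condition))) {
      fc <- compute_fold_changes(st, arm)
      mats[[length(mats) + 1L]] <- collapse_probes_to_genes(fc, probe_to_gene)
    }
  }
  if (!length(mats)) stop("no disease arm found in any study", call. = FALSE)
  mats <- cross_study_quantile_normalize(mats)
  combine_matrices(mats, match = match)
}
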