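# Candidate regulators: interaction hubs scored by how many core genes lie
# within their first/second graph neighborhood, and transcription factors
# scored by how many core genes they target — both against a gene-resampling
# null — plus per-module prioritization.

#' First/second-neighbor hit count
#'
#' Counts the members of `gene_set` lying within graph distance 1 or 2 of
#' the regulator (the union of first and second neighbors); the regulator
#' itself never counts.
#'
#' @param ppi igraph interaction network.
#' @param regulator node id; must be present in the network.
#' @param gene_set character vector of gene ids.
#' @return integer hit count.
#' @export
neighborhood_hit_count <- function(ppi, regulator, gene_set) {
  nb <- neighborhood12(ppi, regulator)
  length(intersect(nb, unique(gene_set)))
}

# N1 union N2 of a node, excluding the node; errors helpfully when absent.
neighborhood12 <- function(ppi, regulator) {
  names <- igraph::V(ppi)$name
  if (!(regulator %in% names)) {
    near <- utils::head(names[order(utils::adist(regulator, names))], 3L)
    stop("regulator '", regulator, "' is not in the network; nearest ids: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  nb <- igraph::ego(ppi, order = 2L, nodes = regulator, mindist = 1L)[[1L]]
  nb$name
}

#' Hub significance by core-gene resampling
#'
#' For each regulator, the statistic is the first/second-neighbor hit count
#' of the core set. The null draws `n_resamples` gene sets of the core set's
#' size from the universe without replacement and recomputes the count;
#' `p = (r + 1)/(B + 1)` with `r` the number of resamples reaching the
#' observed count. Because the draws are exchangeable, this null is exactly
#' hypergeometric in the neighborhood size, which serves as the test oracle.
#'
#' @param ppi igraph interaction network.
#' @param regulators node ids to test (default: all network nodes).
#' @param core_set character vector of core gene ids.
#' @param universe character vector of candidate gene ids
#'   (`|core_set| <= |universe|`).
#' @param n_resamples resampling count B.
#' @param seed integer seed.
#' @param alpha significance cutoff recorded in the `selected` column
#'   (default 0.01).
#' @return data.frame: `gene_id`, `category` (`"ppi_hub"`), `statistic`
#'   (observed hit count), `neighborhood_size`, `empirical_p`, `z_score`,
#'   `selected`, sorted by `empirical_p`.
#' @export
test_hub_significance <- function(ppi, regulators = igraph::V(ppi)$name,
                                  core_set, universe,
                                  n_resamples = 100000L, seed = 1L,
                                  alpha = 0.01) {
  core_set <- unique(as.character(core_set))
  universe <- unique(as.character(universe))
  core_set <- intersect(core_set, universe)
  if (length(core_set) > length(universe))
    stop("core set larger than universe", call. = FALSE)
  nbhds <- lapply(regulators, function(r) neighborhood12(ppi, r))
  names(nbhds) <- regulators
  res <- empirical_set_enrichment(core_set, nbhds, universe,
                                  n_resamples = n_resamples, seed = seed)
  out <- data.frame(gene_id = res$term_id, category = "ppi_hub",
                    statistic = res$observed_count,
                    neighborhood_size = res$term_size,
                    empirical_p = res$empirical_p, z_score = res$z_score,
                    selected = res$empirical_p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$empirical_p, -out$statistic, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Key transcription factors by target-count resampling
#'
#' For each TF, the observed statistic is the number of its targets inside
#' the core set; the null re-draws same-size core sets from the universe
#' (delegating to [empirical_set_enrichment()]). TFs with
#' `empirical_p < alpha` are selected; a TF with no targets in the universe
#' gets p = 1 and is never selected.
#'
#' @param tf_target_map named list: TF id -> target gene vector (e.g. a GMT
#'   with category `tf_targets`).
#' @param core_set character vector of core gene ids.
#' @param universe character vector of candidate gene ids.
#' @param n_resamples resampling count B.
#' @param seed integer seed.
#' @param alpha selection cutoff (default 0.01).
#' @return data.frame: `gene_id` (the TF), `category` (`"tf"`), `statistic`
#'   (target count in core set), `n_targets_universe`, `empirical_p`,
#'   `z_score`, `selected`, sorted by `empirical_p`.
#' @export
identify_key_tfs <- function(tf_target_map, core_set, universe,
                             n_resamples = 100000L, seed = 1L,
                             alpha = 0.01) {
  core_set <- intersect(unique(as.character(core_set)),
                        unique(as.character(universe)))
  res <- empirical_set_enrichment(core_set, tf_target_map, universe,
                                  n_resamples = n_resamples, seed = seed)
  out <- data.frame(gene_id = res$term_id, category = "tf",
                    statistic = res$observed_count,
                    n_targets_universe = res$term_size,
                    empirical_p = res$empirical_p, z_score = res$z_score,
                    selected = res$empirical_p < alpha & res$term_size > 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Prioritize regulator candidates within modules
#'
#' Candidates are associated with every module containing them (hubs) or
#' containing any of their targets (TFs, when `tf_target_map` is given);
#' within each module they are ranked by ascending empirical p, ties broken
#' by larger statistic, then lexicographic gene id — the smallest p value
#' gets the highest priority.
#'
#' @param candidates data.frame from [test_hub_significance()] and/or
#'   [identify_key_tfs()] (rbind-compatible columns `gene_id`, `category`,
#'   `statistic`, `empirical_p`).
#' @param modules named list: module id -> gene vector.
#' @param tf_target_map optional named list used to associate TFs with the
#'   modules their targets fall in.
#' @return data.frame: one row per (candidate, module), with
#'   `rank_within_module`; `attr(, "top_per_module")` holds the rank-1
#'   rows.
#' @export
prioritize_candidates <- function(candidates, modules,
                                  tf_target_map = NULL) {
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    gid <- candidates$gene_id[i]
    member_of <- if (identical(candidates$category[i], "tf") &&
                     !is.null(tf_target_map) && gid %in% names(tf_target_map))
      names(modules)[vapply(modules, function(m)
        length(intersect(m, tf_target_map[[gid]])) > 0L, TRUE)]
    else
      names(modules)[vapply(modules, function(m) gid %in% m, TRUE)]
    for (m in member_of)
      rows[[length(rows) + 1L]] <- cbind(candidates[i, , drop = FALSE],
                                         module_id = m)
  }
  if (!length(rows)) {
    out <- cbind(candidates[0, , drop = FALSE],
                 module_id = character(), rank_within_module = integer())
    attr(out, "top_per_module") <- out
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$module_id, out$empirical_p, -out$statistic, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank_within_module <- stats::ave(seq_len(nrow(out)), out$module_id,
                                       FUN = seq_along)
  rownames(out) <- NULL
  attr(out, "top_per_module") <- out[out$rank_within_module == 1L, ,
                                     drop = FALSE]
  out
}
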