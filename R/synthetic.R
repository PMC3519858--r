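# Synthetic inputs with planted ground truth: multi-study expression with
# shared/dominant up/down gene groups, a scale-free interaction network with
# planted hubs, TF-target maps with planted enriched TFs, annotation sets
# with planted associations, and overlay signatures — everything the
# pipeline consumes, generated with a known answer key.

default_group_sizes <- function(n_genes) {
  # dominant-up ~7% of genes, a realistic disease-dominant fraction for a
  # genome-scale study; the other planted
  # groups sized equally, the rest null
  s <- round(0.07 * n_genes)
  c(shared_up = s, dominant_up = s, shared_down = s, dominant_down = s)
}

#' Generate multi-study expression data with planted DEP groups
#'
#' Per study, log2 intensities are a per-gene baseline `N(8, 1)` plus
#' condition offsets and measurement noise `N(0, noise_sd^2)`. Shared
#' groups are shifted by `+/-effect_size` in both disease arms; dominant
#' groups only in the primary arm; null genes are unshifted. Each study gets
#' a small multiplicative scale jitter so that cross-study quantile
#' normalization has real work to do.
#'
#' @param n_studies number of studies (default 3).
#' @param n_genes genes per study (default 2000).
#' @param samples_per_arm samples in each of the normal / primary /
#'   comparator arms (default 5).
#' @param effect_size log2-unit shift of planted groups (default 2).
#' @param noise_sd per-measurement noise sd (default 0.5).
#' @param group_sizes named integer vector for `shared_up`, `dominant_up`,
#'   `shared_down`, `dominant_down`; remaining genes are null.
#' @param scale_jitter half-width of the uniform per-study scale factor.
#' @param seed integer seed.
#' @return list with `studies` (list of [expression_study()]),
#'   `probe_to_gene` (identity map probe -> gene) and `truth` (a
#'   `ground_truth` list with `planted_groups` and `seeds_used`).
#' @export
generate_multistudy_expression <- function(n_studies = 3L, n_genes = 2000L,
                                           samples_per_arm = 5L,
                                           effect_size = 2,
                                           noise_sd = 0.5,
                                           group_sizes =
                                             default_group_sizes(n_genes),
                                           scale_jitter = 0.1,
                                           seed = 1L) {
  if (sum(group_sizes) > n_genes)
    stop("group sizes exceed n_genes", call. = FALSE)
  if (n_studies < 1L || samples_per_arm < 1L || n_genes < 1L)
    stop("degenerate sizes", call. = FALSE)
  genes <- sprintf("g%05d", seq_len(n_genes))
  groups <- c("shared_up", "dominant_up", "shared_down", "dominant_down")
  planted <- with_seed(derive_seed(seed, 0L), {
    idx <- sample.int(n_genes, sum(group_sizes))
    split(genes[idx],
          rep(factor(groups, levels = groups), group_sizes[groups]))
  })
  planted <- lapply(planted, as.character)
  planted$null <- setdiff(genes, unlist(planted))
  arms <- c("normal", "disease_primary", "disease_comparator")
  baseline <- with_seed(derive_seed(seed, 1L),
                        stats::setNames(stats::rnorm(n_genes, 8, 1), genes))
  studies <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    studies[[s]] <- with_seed(derive_seed(seed, 10L + s), {
      condition <- rep(arms, each = samples_per_arm)
      n_samp <- length(condition)
      shift <- matrix(0, n_genes, n_samp, dimnames = list(genes, NULL))
      prim <- condition == "disease_primary"
      comp <- condition == "disease_comparator"
      shift[planted$shared_up, prim | comp] <- effect_size
      shift[planted$dominant_up, prim] <- effect_size
      shift[planted$shared_down, prim | comp] <- -effect_size
      shift[planted$dominant_down, prim] <- -effect_size
      scale <- 1 + stats::runif(1, -scale_jitter, scale_jitter)
      vals <- (baseline + shift +
                 matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd),
                        n_genes)) * scale
      rownames(vals) <- paste0("p_", genes)
      colnames(vals) <- sprintf("s%d_%02d", s, seq_len(n_samp))
      expression_study(sprintf("study%d", s), vals, condition)
    })
  }
  truth <- structure(list(planted_groups = planted, seeds_used = seed),
                     class = "ground_truth")
  list(studies = studies,
       probe_to_gene = stats::setNames(genes, paste0("p_", genes)),
       truth = truth)
}

#' Generate a scale-free interaction network with planted hubs
#'
#' A preferential-attachment (Barabasi-Albert) graph over the gene pool;
#' `n_hubs` nodes are then planted by wiring each to every member of
#' `core_genes` independently with probability `core_bias` (so a planted
#' hub's first neighborhood is enriched for core genes beyond its degree
#' share).
#'
#' @param genes character vector naming the nodes.
#' @param attach_m edges added per new node (`attach_m = 1` gives a tree).
#' @param n_hubs number of planted hubs.
#' @param core_genes gene set the hubs are biased toward.
#' @param core_bias per-core-gene wiring probability for each hub.
#' @param hub_pool candidate nodes for the planted hubs; defaults to the
#'   non-core nodes. Pass (a subset of) `core_genes` to plant hubs inside
#'   the core set itself.
#' @param seed integer seed.
#' @return list with `network` (igraph) and `truth` (`ground_truth` with
#'   `planted_hubs`).
#' @export
generate_interaction_network <- function(genes, attach_m = 2L, n_hubs = 5L,
                                         core_genes = character(),
                                         core_bias = 0.5, hub_pool = NULL,
                                         seed = 1L) {
  n <- length(genes)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  with_seed(derive_seed(seed, 0L), {
    g <- igraph::sample_pa(n, m = attach_m, directed = FALSE)
    igraph::V(g)$name <- sample(genes)
    hubs <- character()
    if (n_hubs > 0L) {
      pool <- hub_pool %||% setdiff(igraph::V(g)$name, core_genes)
      pool <- intersect(pool, igraph::V(g)$name)
      hubs <- sample(pool, min(n_hubs, length(pool)))
      core_in <- intersect(core_genes, igraph::V(g)$name)
      for (h in hubs) {
        wired <- core_in[stats::runif(length(core_in)) < core_bias]
        wired <- setdiff(wired, h)
        if (length(wired))
          g <- igraph::add_edges(g, rbind(h, wired))
      }
    }
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    list(network = g,
         truth = structure(list(planted_hubs = sort(hubs),
                                seeds_used = seed),
                           class = "ground_truth"))
  })
}

#' Generate a TF-target map with planted enriched TFs
#'
#' Background TFs draw their targets uniformly from the universe; the first
#' `n_planted` TFs draw a fraction `core_overlap_fraction` of their targets
#' from `core_genes` and the rest from the remainder of the universe.
#'
#' @param universe character vector of candidate target genes.
#' @param n_tfs total number of TFs.
#' @param targets_per_tf targets drawn per TF.
#' @param n_planted number of planted (core-enriched) TFs.
#' @param core_genes core gene set.
#' @param core_overlap_fraction fraction of a planted TF's targets drawn
#'   from the core set.
#' @param seed integer seed.
#' @return list with `tf_targets` (named list, GMT-compatible) and `truth`
#'   (`ground_truth` with `planted_tfs`).
#' @export
generate_tf_target_map <- function(universe, n_tfs = 30L,
                                   targets_per_tf = 50L, n_planted = 3L,
                                   core_genes = character(),
                                   core_overlap_fraction = 0.4,
                                   seed = 1L) {
  if (n_tfs == 0L)
    return(list(tf_targets = stats::setNames(list(), character()),
                truth = structure(list(planted_tfs = character(),
                                       seeds_used = seed),
                                  class = "ground_truth")))
  core_in <- intersect(core_genes, universe)
  rest <- setdiff(universe, core_in)
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  planted <- tfs[seq_len(min(n_planted, n_tfs))]
  sets <- with_seed(derive_seed(seed, 0L), {
    lapply(tfs, function(tf) {
      if (tf %in% planted && length(core_in)) {
        n_core <- min(round(core_overlap_fraction * targets_per_tf),
                      length(core_in))
        sort(c(sample(core_in, n_core),
               sample(rest, min(targets_per_tf - n_core, length(rest)))))
      } else {
        sort(sample(universe, min(targets_per_tf, length(universe))))
      }
    })
  })
  names(sets) <- tfs
  attr(sets, "description") <- stats::setNames(rep("tf_targets", n_tfs), tfs)
  list(tf_targets = sets,
       truth = structure(list(planted_tfs = planted, seeds_used = seed),
                         class = "ground_truth"))
}

#' Generate process/disease annotation sets with planted associations
#'
#' Each module term draws a fraction `from_group_fraction` of its genes from
#' a designated planted group (default the dominant-up group) and the rest
#' from the remaining genes, so the group is hypergeometrically enriched in
#' every term. With `disjoint = TRUE` terms are pairwise disjoint.
#'
#' @param module_labels character vector of term ids (e.g. the sixteen
#'   module labels `AP, TC, BC, IG, CA, NK, IC, CK, CMH, TLR, AF, JS, CC,
#'   CDS, ECM, MR`).
#' @param universe character vector of all genes.
#' @param target_group character vector, the planted group to enrich.
#' @param genes_per_module term size.
#' @param from_group_fraction fraction of each term drawn from the group.
#' @param disjoint draw terms without cross-term overlap.
#' @param category description written into the GMT attribute.
#' @param seed integer seed.
#' @return list with `annotations` (named list) and `truth` (`ground_truth`
#'   with `planted_module_map`).
#' @export
generate_annotation_sets <- function(module_labels, universe, target_group,
                                     genes_per_module = 20L,
                                     from_group_fraction = 0.8,
                                     disjoint = TRUE,
                                     category = "process", seed = 1L) {
  if (!length(module_labels))
    return(list(annotations = stats::setNames(list(), character()),
                truth = structure(list(planted_module_map = list(),
                                       seeds_used = seed),
                                  class = "ground_truth")))
  grp <- intersect(target_group, universe)
  rest <- setdiff(universe, grp)
  sets <- with_seed(derive_seed(seed, 0L), {
    out <- vector("list", length(module_labels))
    for (i in seq_along(module_labels)) {
      n_grp <- min(round(from_group_fraction * genes_per_module),
                   length(grp))
      picked <- c(sample(grp, n_grp),
                  sample(rest, min(genes_per_module - n_grp, length(rest))))
      if (disjoint) {
        grp <- setdiff(grp, picked)
        rest <- setdiff(rest, picked)
      }
      out[[i]] <- sort(picked)
    }
    out
  })
  names(sets) <- module_labels
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " annotation term(s) left empty by pool exhaustion",
            call. = FALSE)
    sets <- sets[!empty]
  }
  attr(sets, "description") <- stats::setNames(
    rep(category, length(sets)), names(sets))
  list(annotations = sets,
       truth = structure(list(planted_module_map = sets, seeds_used = seed),
                         class = "ground_truth"))
}

#' Generate overlay signature gene sets
#'
#' For each label, covers each module's genes at the given per-module rate;
#' `coverage_per_module` may be a single rate or a vector named by module. A
#' coverage of 0 everywhere plus `n_outside` yields a signature disjoint
#' from the network (a "blood-cell-like" negative control whose module
#' scores are all ~0).
#'
#' @param module_map named list: module id -> gene vector.
#' @param labels character vector of signature names.
#' @param coverage_per_module per-module coverage rate(s) in \[0, 1\].
#' @param n_outside genes drawn from `outside_pool` (ids not in any module).
#' @param outside_pool candidate off-network genes.
#' @param seed integer seed.
#' @return named list of signature gene sets (GMT-compatible, category
#'   `signature`).
#' @export
generate_overlay_signatures <- function(module_map, labels,
                                        coverage_per_module = 0.5,
                                        n_outside = 0L,
                                        outside_pool = character(),
                                        seed = 1L) {
  sets <- with_seed(derive_seed(seed, 0L), {
    lapply(seq_along(labels), function(i) {
      cov <- coverage_per_module
      picked <- unlist(lapply(names(module_map), function(m) {
        rate <- if (length(cov) > 1L) cov[[m]] %||% 0 else cov
        g <- module_map[[m]]
        if (rate <= 0 || !length(g)) return(character())
        sample(g, max(0L, round(rate * length(g))))
      }))
      extra <- if (n_outside > 0L && length(outside_pool))
        sample(outside_pool, min(n_outside, length(outside_pool)))
      else character()
      sort(unique(c(picked, extra)))
    })
  })
  names(sets) <- labels
  attr(sets, "description") <- stats::setNames(
    rep("signature", length(sets)), labels)
  sets
}

#' Generate and write every pipeline input with ground truth
#'
#' Runs all generators with consistent defaults and, when `out_dir` is
#' given, writes expression TSVs, a sample sheet, a probe map, a PPI edge
#' list, process/disease/TF/signature GMTs, a universe list, and the ground
#' truth as JSON. The generator defaults are the package's reference study
#' conditions.
#'
#' @param seed integer master seed.
#' @param out_dir optional output directory (created if needed).
#' @param n_studies,n_genes,samples_per_arm,effect_size,noise_sd,group_sizes
#'   passed to [generate_multistudy_expression()].
#' @param module_labels labels for the process modules (default the sixteen
#'   two/three-letter labels).
#' @param n_hubs,core_bias passed to [generate_interaction_network()].
#' @param n_tfs,n_planted_tfs,tf_core_fraction passed to
#'   [generate_tf_target_map()].
#' @return list with `studies`, `probe_to_gene`, `network`, `tf_targets`,
#'   `annotations`, `overlays`, `universe`, `truth` (merged
#'   `ground_truth`), and `files` (paths, when written).
#' @export
simulate_ra_inputs <- function(seed = 1L, out_dir = NULL,
                               n_studies = 3L, n_genes = 2000L,
                               samples_per_arm = 5L, effect_size = 2,
                               noise_sd = 0.5,
                               group_sizes = default_group_sizes(n_genes),
                               module_labels = c("AP", "TC", "BC", "IG",
                                                 "CA", "NK", "IC", "CK",
                                                 "CMH", "TLR", "AF", "JS",
                                                 "CC", "CDS", "ECM", "MR"),
                               n_hubs = 5L, core_bias = 0.5,
                               n_tfs = 30L, n_planted_tfs = 3L,
                               tf_core_fraction = 0.4) {
  expr <- generate_multistudy_expression(
    n_studies = n_studies, n_genes = n_genes,
    samples_per_arm = samples_per_arm, effect_size = effect_size,
    noise_sd = noise_sd, group_sizes = group_sizes, seed = seed)
  universe <- sort(unname(expr$probe_to_gene))
  core <- expr$truth$planted_groups$dominant_up
  net <- generate_interaction_network(universe, attach_m = 2L,
                                      n_hubs = n_hubs, core_genes = core,
                                      core_bias = core_bias,
                                      hub_pool = core,
                                      seed = derive_seed(seed, 21L))
  tf <- generate_tf_target_map(universe, n_tfs = n_tfs,
                               targets_per_tf = 50L,
                               n_planted = n_planted_tfs,
                               core_genes = core,
                               core_overlap_fraction = tf_core_fraction,
                               seed = derive_seed(seed, 22L))
  genes_per_module <- max(3L, min(20L,
                                  n_genes %/% max(length(module_labels), 1L)))
  # modules may share genes, as real process annotations do
  ann <- generate_annotation_sets(module_labels, universe, core,
                                  genes_per_module = genes_per_module,
                                  from_group_fraction = 0.8,
                                  disjoint = FALSE,
                                  seed = derive_seed(seed, 23L))
  overlays <- generate_overlay_signatures(
    ann$truth$planted_module_map,
    labels = c("cell_like_up", "blood_like_up"),
    coverage_per_module = 0.5, seed = derive_seed(seed, 24L))
  off_pool <- setdiff(universe, unlist(ann$annotations))
  overlays$blood_like_up <- generate_overlay_signatures(
    ann$truth$planted_module_map, labels = "blood_like_up",
    coverage_per_module = 0, n_outside = 100L, outside_pool = off_pool,
    seed = derive_seed(seed, 25L))[[1L]]
  truth <- structure(list(
    planted_groups = expr$truth$planted_groups,
    planted_hubs = net$truth$planted_hubs,
    planted_tfs = tf$truth$planted_tfs,
    planted_module_map = ann$truth$planted_module_map,
    seeds_used = seed), class = "ground_truth")
  out <- list(studies = expr$studies, probe_to_gene = expr$probe_to_gene,
              network = net$network, tf_targets = tf$tf_targets,
              annotations = ann$annotations, overlays = overlays,
              universe = universe, truth = truth)
  if (!is.null(out_dir)) out$files <- write_simulated_inputs(out, out_dir)
  out
}

# Writes every simulated input in its exchange format; returns the paths.
write_simulated_inputs <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  sheet <- list()
  for (st in sim$studies) {
    p <- file.path(out_dir, paste0("expr_", st$study_id, ".tsv"))
    write_expression_tsv(st$values, p, id_col = "probe_id")
    files[[paste0("expr_", st$study_id)]] <- p
    sheet[[st$study_id]] <- data.frame(
      sample_id = colnames(st$values), condition = st$condition,
      study_id = st$study_id, stringsAsFactors = FALSE)
  }
  files$samples <- file.path(out_dir, "samples.tsv")
  utils::write.table(do.call(rbind, sheet), files$samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$probe_map <- file.path(out_dir, "probe_map.tsv")
  utils::write.table(
    data.frame(probe_id = names(sim$probe_to_gene),
               gene_id = unname(sim$probe_to_gene)),
    files$probe_map, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  files$ppi <- file.path(out_dir, "ppi.tsv")
  el <- igraph::as_edgelist(sim$network)
  utils::write.table(data.frame(a = el[, 1], b = el[, 2]), files$ppi,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  files$tf_gmt <- write_gmt(sim$tf_targets,
                            file.path(out_dir, "tf_targets.gmt"))
  files$process_gmt <- write_gmt(sim$annotations,
                                 file.path(out_dir, "processes.gmt"))
  files$overlay_gmt <- write_gmt(sim$overlays,
                                 file.path(out_dir, "overlays.gmt"))
  files$universe <- write_gene_list(sim$universe,
                                    file.path(out_dir, "universe.txt"))
  files$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(unclass(sim$truth), files$truth, auto_unbox = TRUE,
                       pretty = TRUE)
  lapply(files, normalizePath)
}
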