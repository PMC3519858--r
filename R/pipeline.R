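# Configuration-driven orchestration of the full pipeline:
# preprocess -> DEP discovery -> enrichment -> network scores -> regulators,
# with per-stage seeds, structured logging and a checksummed manifest.

#' Build a validated pipeline configuration
#'
#' Thresholds default to full-scale study defaults (k = 30 clusters, 95th
#' percentile cutoffs, membership alpha 0.05, TF/hub alpha 0.01,
#' B = 100,000 resamples); `fast = TRUE` switches to the light profile
#' (B = 10,000, 20 permutations) used for routine runs. A configuration can
#' also be read from YAML via `config_file`, with `...` overriding
#' individual keys.
#'
#' @param inputs named list of input paths: `expr` (character vector of
#'   expression TSVs), `samples`, `probe_map`, `ppi`, `process_gmt`,
#'   `tf_gmt`, `overlay_gmt`, `universe` (optional; defaults to the
#'   combined-matrix genes).
#' @param out_dir output directory.
#' @param seed master integer seed; every stochastic stage derives its own
#'   seed from it.
#' @param config_file optional YAML file of defaults.
#' @param fast use the light resampling profile.
#' @param ... overrides for any of: `n_clusters`, `alpha_membership`,
#'   `alpha_enrichment`, `alpha_regulator`, `n_permutations`, `percentile`,
#'   `n_resamples`, `match`, `n_restarts`, `dominant_max_comparator`,
#'   `shared_min_fraction`, `min_primary_studies`.
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(inputs, out_dir, seed,
                            config_file = NULL, fast = FALSE, ...) {
  cfg <- list(
    n_clusters = 30L, alpha_membership = 0.05, alpha_enrichment = 0.05,
    alpha_regulator = 0.01, n_permutations = if (fast) 20L else 100L,
    percentile = 95, n_resamples = if (fast) 10000L else 100000L,
    match = "intersection", n_restarts = 5L,
    dominant_max_comparator = 0.2, shared_min_fraction = 0.2,
    min_primary_studies = 2L)
  if (!is.null(config_file))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(config_file))
  cfg <- utils::modifyList(cfg, list(...))
  cfg$inputs <- inputs
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  for (a in c("alpha_membership", "alpha_enrichment", "alpha_regulator"))
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1)
      stop(a, " must be in (0, 1)", call. = FALSE)
  if (is.na(cfg$seed)) stop("an explicit seed is required", call. = FALSE)
  need <- c("expr", "samples", "probe_map", "ppi", "process_gmt", "tf_gmt",
            "overlay_gmt")
  missing_keys <- setdiff(need, names(inputs))
  if (length(missing_keys))
    stop("missing input path(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  absent <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Executes preprocess, DEP discovery, disease/process enrichment of the
#' core genes, perturbed-network reconstruction with module scores, and
#' regulator identification, writing each stage's outputs and a manifest
#' JSON with parameters, seeds and md5 checksums. Outputs are byte-stable
#' under a fixed configuration and seed. On a stage failure a partial
#' manifest (with the failure recorded) is still written before the error
#' propagates.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  manifest <- list(
    parameters = unclass(config)[setdiff(names(config), "inputs")],
    inputs = config$inputs, stages = list())
  outputs <- character()
  t_all <- Sys.time()
  write_manifest <- function() {
    chk <- if (length(outputs)) as.list(tools::md5sum(sort(outputs)))
           else list()
    names(chk) <- basename(names(chk) %||% character())
    manifest$checksums <<- chk
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    pipeline_log(con, name, "started")
    value <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(
        status = "failed", error = conditionMessage(e))
      write_manifest()
      pipeline_log(con, name, paste("FAILED:", conditionMessage(e)))
      stop(e)
    })
    # timing goes to the log only, so the manifest is byte-stable
    manifest$stages[[name]] <<- list(status = "completed")
    elapsed <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    pipeline_log(con, name, sprintf("completed in %ss", elapsed))
    value
  }
  out_path <- function(f) {
    p <- file.path(config$out_dir, f)
    outputs <<- union(outputs, p)
    p
  }

  combined <- run_stage("preprocess", function() {
    sheet <- read_sample_sheet(config$inputs$samples)
    pmap <- read_probe_map(config$inputs$probe_map)
    studies <- lapply(config$inputs$expr, function(p) {
      vals <- read_expression_tsv(p)
      rows <- sheet[match(colnames(vals), sheet$sample_id), ]
      if (anyNA(rows$study_id))
        stop("samples in ", p, " missing from the sample sheet")
      sid <- unique(rows$study_id)
      if (length(sid) != 1L)
        stop("expression file ", p, " mixes studies")
      expression_study(sid, vals, rows$condition)
    })
    combined <- preprocess_studies(studies, pmap, match = config$match)
    write_expression_tsv(combined$values, out_path("combined_fc.tsv"),
                         id_col = "gene_id")
    combined
  })

  dep <- run_stage("dep_discovery", function() {
    dep <- discover_deps(
      combined, n_clusters = config$n_clusters,
      alpha = config$alpha_membership,
      n_permutations = config$n_permutations,
      percentile = config$percentile, seed = derive_seed(config$seed, 2L),
      n_restarts = config$n_restarts,
      dominant_max_comparator = config$dominant_max_comparator,
      shared_min_fraction = config$shared_min_fraction,
      min_primary_studies = config$min_primary_studies)
    cl <- dep$clusters
    flat <- data.frame(cluster = cl$cluster, direction = cl$direction,
                       n_members = cl$n_members, n_samples = cl$n_samples,
                       significant = cl$significant,
                       class_label = cl$class_label,
                       members = vapply(cl$members, paste, "",
                                        collapse = ","),
                       stringsAsFactors = FALSE)
    utils::write.table(flat, out_path("dep_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    thr <- dep$thresholds
    jsonlite::write_json(
      thr[c("gene_count_threshold", "sample_count_threshold",
            "basis_cutoff", "activation_cutoff", "percentile",
            "n_permutations")],
      out_path("thresholds.json"), auto_unbox = TRUE, digits = NA)
    write_gene_list(dep$core_genes, out_path("core_genes.txt"))
    dep
  })
  if (!length(dep$core_genes))
    pipeline_log(con, "dep_discovery", "note: empty core gene set")

  universe <- if (!is.null(config$inputs$universe))
    read_gene_list(config$inputs$universe) else combined$gene_ids

  run_stage("enrichment", function() {
    ann <- read_gmt(config$inputs$process_gmt)
    query <- intersect(dep$core_genes, universe)
    enr <- empirical_set_enrichment(query, ann, universe,
                                    n_resamples = config$n_resamples,
                                    seed = derive_seed(config$seed, 3L))
    utils::write.table(enr, out_path("core_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    enr
  })

  scores <- run_stage("network_scores", function() {
    ppi <- load_interactions(config$inputs$ppi)
    ann <- read_gmt(config$inputs$process_gmt)
    overlays <- read_gmt(config$inputs$overlay_gmt)
    net <- reconstruct_perturbed_network(dep$core_genes, ann, ppi)
    modules <- assign_network_modules(net, ann)
    write_sif(net, out_path("perturbed_network.sif"))
    write_graphml(net, out_path("perturbed_network.graphml"))
    mod_df <- data.frame(
      module_id = rep(names(modules), lengths(modules)),
      gene_id = unlist(modules, use.names = FALSE),
      stringsAsFactors = FALSE)
    utils::write.table(mod_df, out_path("modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mes <- module_score_table(modules, overlays, igraph::vcount(net),
                              max(length(dep$core_genes), 1L))
    utils::write.table(mes, out_path("module_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(ppi = ppi, network = net, modules = modules)
  })

  run_stage("regulators", function() {
    tf_map <- read_gmt(config$inputs$tf_gmt)
    tfs <- identify_key_tfs(tf_map, dep$core_genes, universe,
                            n_resamples = config$n_resamples,
                            seed = derive_seed(config$seed, 4L),
                            alpha = config$alpha_regulator)
    pool <- intersect(igraph::V(scores$network)$name,
                      igraph::V(scores$ppi)$name)
    hubs <- test_hub_significance(scores$ppi, pool, dep$core_genes,
                                  universe,
                                  n_resamples = config$n_resamples,
                                  seed = derive_seed(config$seed, 5L),
                                  alpha = config$alpha_regulator)
    cand <- rbind(
      hubs[c("gene_id", "category", "statistic", "empirical_p")],
      tfs[c("gene_id", "category", "statistic", "empirical_p")])
    ranked <- prioritize_candidates(cand[cand$empirical_p <
                                           config$alpha_regulator, ],
                                    scores$modules, tf_target_map = tf_map)
    utils::write.table(tfs, out_path("key_tfs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(hubs, out_path("hub_candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ranked, out_path("ranked_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ranked
  })

  write_manifest()
  pipeline_log(con, "pipeline",
               sprintf("5 stages completed in %ss",
                       round(as.numeric(difftime(Sys.time(), t_all,
                                                 units = "secs")), 2)))
  invisible(manifest)
}
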