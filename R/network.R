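# Interaction-network handling: loading edge lists, reconstructing the
# disease-perturbed subnetwork around the core genes, module assignment, and
# the module-level overlay scores (MES, target enrichment score).

#' Load an undirected interaction network from a TSV or SIF edge list
#'
#' TSV lines are `gene_a<TAB>gene_b[<TAB>source]`; SIF lines are
#' `gene_a<SEP>interaction_type<SEP>gene_b` (tab or whitespace separated).
#' Self-loops are dropped and edges deduplicated ignoring order; the counts
#' are kept in the load report.
#'
#' @param path path to the edge list.
#' @param format `"tsv"` or `"sif"`; `"auto"` picks SIF for `.sif` files.
#' @return an igraph undirected graph; `attr(, "load_report")` lists
#'   `n_nodes`, `n_edges`, `n_self_loops`, `n_duplicates`.
#' @export
load_interactions <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty interaction file: ", path, call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    attr(g, "load_report") <- list(n_nodes = 0L, n_edges = 0L,
                                   n_self_loops = 0L, n_duplicates = 0L)
    return(g)
  }
  if (format == "sif") {
    fields <- strsplit(lines, "[\t ]+")
    bad <- which(vapply(fields, length, 1L) < 3L)
    if (length(bad))
      stop("malformed SIF line(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    edges <- data.frame(a = vapply(fields, `[[`, "", 1L),
                        b = vapply(fields, `[[`, "", 3L),
                        source = vapply(fields, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (identical(tolower(fields[[1]][1]), "gene_a"))
      fields <- fields[-1L]
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad))
      stop("malformed edge line(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    edges <- data.frame(a = vapply(fields, `[[`, "", 1L),
                        b = vapply(fields, `[[`, "", 2L),
                        source = vapply(fields, function(f)
                          if (length(f) >= 3L) f[[3L]] else "pp", ""),
                        stringsAsFactors = FALSE)
  }
  interaction_network(edges)
}

#' Build an interaction network from an edge data.frame
#'
#' @param edges data.frame with columns `a`, `b` and optionally `source`.
#' @return undirected igraph graph with a `load_report` attribute.
#' @export
interaction_network <- function(edges) {
  self <- edges$a == edges$b
  edges <- edges[!self, , drop = FALSE]
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  edges <- data.frame(a = lo[!dup], b = hi[!dup],
                      source = (edges$source %||% rep("pp", nrow(edges)))[!dup],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  attr(g, "load_report") <- list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    n_self_loops = sum(self), n_duplicates = sum(dup))
  g
}

#' Reconstruct the disease-perturbed subnetwork
#'
#' Seeds are the core genes annotated to at least one of the configured
#' module terms; interactors are the remaining core genes adjacent to a seed
#' in the interaction network (a core gene that is annotated is always a
#' seed, never an interactor; interactors are restricted to the core set).
#' The result is the subgraph induced on seeds and interactors.
#'
#' @param core_genes character vector of core gene ids.
#' @param process_annotations named list of term gene sets defining the
#'   modules (e.g. from [read_gmt()]).
#' @param ppi an igraph interaction network.
#' @return an igraph graph with a vertex attribute `role` in
#'   `{"seed", "interactor"}`.
#' @export
reconstruct_perturbed_network <- function(core_genes, process_annotations,
                                          ppi) {
  core_genes <- unique(as.character(core_genes))
  annotated <- unique(unlist(process_annotations))
  seeds <- intersect(core_genes, annotated)
  if (!length(seeds)) stop("no core gene is annotated to any module term",
                           call. = FALSE)
  in_ppi <- intersect(seeds, igraph::V(ppi)$name)
  nbrs <- if (length(in_ppi))
    unique(unlist(lapply(igraph::adjacent_vertices(ppi, in_ppi), names)))
  else character()
  interactors <- setdiff(intersect(core_genes, nbrs), seeds)
  nodes <- union(seeds, interactors)
  present <- intersect(nodes, igraph::V(ppi)$name)
  g <- igraph::induced_subgraph(ppi, present)
  # annotated seeds outside the ppi still belong to the network as isolates
  missing <- setdiff(seeds, present)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  igraph::V(g)$role <- ifelse(igraph::V(g)$name %in% seeds,
                              "seed", "interactor")
  g
}

#' Assign network modules
#'
#' Annotated nodes join every module whose term they carry; unannotated
#' interactors join the module(s) of their adjacent seeds by majority (ties
#' join all tied modules). A gene may belong to several modules.
#'
#' @param network a reconstructed igraph network (with `role` attribute).
#' @param process_annotations named list: module id -> term gene set.
#' @return named list: module id -> character vector of member node ids;
#'   modules with no member in the network are dropped.
#' @export
assign_network_modules <- function(network, process_annotations) {
  nodes <- igraph::V(network)$name
  modules <- lapply(process_annotations, function(g) intersect(nodes, g))
  direct <- modules
  annotated <- unique(unlist(direct))
  unassigned <- setdiff(nodes, annotated)
  for (v in unassigned) {
    nb <- names(igraph::neighbors(network, v))
    nb_seeds <- nb[nb %in% annotated]
    if (!length(nb_seeds)) next
    tally <- vapply(direct, function(m) length(intersect(m, nb_seeds)), 1L)
    top <- names(tally)[tally == max(tally) & tally > 0L]
    for (m in top) modules[[m]] <- c(modules[[m]], v)
  }
  modules <- lapply(modules, function(m) sort(unique(m)))
  modules[lengths(modules) > 0L]
}

#' Module enrichment score (MES)
#'
#' `MES = (overlap / module_size) / (network_size / core_set_size)`: the
#' fraction of a module covered by the overlay gene set, normalized by the
#' network-to-core size ratio — implemented in exactly this form. Set
#' `conventional = TRUE` for the reciprocal-background variant
#' `(overlap / module_size) / (core_set_size / network_size)` for
#' comparison.
#'
#' @param module_genes character vector, the module's genes.
#' @param overlay character vector, the overlay signature gene set.
#' @param network_size total genes in the perturbed network.
#' @param core_set_size total core (disease-dominant up-regulated) genes.
#' @param module_id optional label carried into the result.
#' @param overlay_label optional label carried into the result.
#' @param conventional reciprocal-background variant flag.
#' @return one-row data.frame: `module_id`, `overlay_label`,
#'   `overlap_count`, `module_size`, `score`.
#' @export
module_enrichment_score <- function(module_genes, overlay, network_size,
                                    core_set_size, module_id = NA_character_,
                                    overlay_label = NA_character_,
                                    conventional = FALSE) {
  m <- length(unique(module_genes))
  if (m == 0L) stop("empty module", call. = FALSE)
  if (network_size <= 0 || core_set_size <= 0)
    stop("network_size and core_set_size must be positive", call. = FALSE)
  ov <- length(intersect(unique(module_genes), unique(overlay)))
  bg <- if (conventional) core_set_size / network_size
        else network_size / core_set_size
  data.frame(module_id = module_id, overlay_label = overlay_label,
             overlap_count = ov, module_size = m,
             score = (ov / m) / bg, stringsAsFactors = FALSE)
}

#' Target enrichment score of a TF in a module
#'
#' The fraction of the module's genes that are targets of the TF, in
#' \[0, 1\].
#'
#' @param module_genes character vector, the module's genes.
#' @param tf_targets character vector, the TF's targets.
#' @param module_id,tf_id optional labels.
#' @return one-row data.frame: `module_id`, `overlay_label` (the TF),
#'   `overlap_count`, `module_size`, `score`.
#' @export
target_enrichment_score <- function(module_genes, tf_targets,
                                    module_id = NA_character_,
                                    tf_id = NA_character_) {
  m <- length(unique(module_genes))
  if (m == 0L) stop("empty module", call. = FALSE)
  ov <- length(intersect(unique(module_genes), unique(tf_targets)))
  data.frame(module_id = module_id, overlay_label = tf_id,
             overlap_count = ov, module_size = m, score = ov / m,
             stringsAsFactors = FALSE)
}

#' Overlay a signature gene set on the network
#'
#' Flags each node by overlay membership and summarizes the coverage.
#'
#' @param network an igraph network.
#' @param overlay character vector of gene ids.
#' @param label attribute name for the flag (default `"overlay"`).
#' @return the network with a logical vertex attribute `label`;
#'   `attr(, "overlay_summary")` holds `label`, `overlap_count`,
#'   `network_size`, `fraction`.
#' @export
overlay_signature <- function(network, overlay, label = "overlay") {
  flag <- igraph::V(network)$name %in% unique(overlay)
  network <- igraph::set_vertex_attr(network, label, value = flag)
  attr(network, "overlay_summary") <- list(
    label = label, overlap_count = sum(flag),
    network_size = igraph::vcount(network),
    fraction = if (igraph::vcount(network)) mean(flag) else 0)
  network
}

#' MES table for a set of modules and overlay signatures
#'
#' @param modules named list: module id -> gene vector.
#' @param overlays named list: overlay label -> gene vector.
#' @param network_size,core_set_size see [module_enrichment_score()].
#' @param conventional reciprocal-background variant flag.
#' @return data.frame with one row per (module, overlay).
#' @export
module_score_table <- function(modules, overlays, network_size,
                               core_set_size, conventional = FALSE) {
  rows <- list()
  for (ov in names(overlays))
    for (m in names(modules))
      rows[[length(rows) + 1L]] <- module_enrichment_score(
        modules[[m]], overlays[[ov]], network_size, core_set_size,
        module_id = m, overlay_label = ov, conventional = conventional)
  do.call(rbind, rows)
}

#' Export a network as SIF
#'
#' @param network igraph graph.
#' @param path output path.
#' @param type interaction type written in the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path, type = "pp") {
  el <- igraph::as_edgelist(network)
  lines <- if (nrow(el)) paste(el[, 1], type, el[, 2], sep = "\t")
           else character()
  iso <- igraph::V(network)$name[igraph::degree(network) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a network as GraphML (node attributes preserved)
#'
#' @param network igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
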