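# Readers and writers for the plain-text exchange formats the pipeline uses:
# expression TSV (first column = probe/gene id, header = sample ids), sample
# sheets, two-column probe maps, GMT gene-set collections, one-gene-per-line
# lists, and SIF edge lists.

#' Read an expression table
#'
#' Tab-separated, first column the probe (or gene) identifier, remaining
#' columns one per sample with sample ids in the header row.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with probe ids as rownames, sample ids as colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression table needs an id column plus >=1 sample column",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate probe/gene ids in ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression/fold-change matrix as TSV
#'
#' @param values numeric matrix with row and column names.
#' @param path output path.
#' @param id_col header name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(values, path, id_col = "id") {
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `condition`, `study_id`. Conditions must be
#' drawn from `normal`, `disease_primary`, `disease_comparator`, `treated`,
#' `control`.
#'
#' @param path path to the sheet.
#' @return data.frame with those three character columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "study_id")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$condition), condition_levels())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df[need]
}

condition_levels <- function() {
  c("normal", "disease_primary", "disease_comparator", "treated", "control")
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_id`), with or without a header row.
#'
#' @param path path to the map.
#' @return named character vector: `map[probe_id] == gene_id`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("probe map needs two columns", call. = FALSE)
  if (identical(tolower(df[1, 1]), "probe_id")) df <- df[-1L, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a gene list (one id per line)
#'
#' @param path path to the list.
#' @return character vector of unique ids, blank lines dropped.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  unique(trimws(x[nzchar(trimws(x))]))
}

#' Write a gene list (one id per line)
#' @param genes character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: tab-separated, per line `term_id`, `description`, then the
#' member genes. The description slot doubles as the category label
#' (`process`, `disease`, `tf_targets`, `signature`) where relevant.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of gene ids; term descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("malformed GMT line(s) (need term, description, >=1 gene): ",
         paste(which(short), collapse = ", "), call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), ids)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of term descriptions;
#'   defaults to the `description` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  description <- description %||% attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, description[[id]] %||% "na", sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
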