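# Empirical resampling gene-set enrichment with an exact hypergeometric
# oracle and the inverse-normal Z transform of the empirical p-value.

#' Empirical resampling enrichment of a query gene set
#'
#' For each annotation term, the observed statistic is the overlap between
#' the query and the term (both intersected with the universe). The null is
#' built by drawing `n_resamples` same-size gene sets from the universe
#' without replacement and counting overlaps; the one-tailed empirical
#' p-value is `(r + 1) / (B + 1)` where `r` is the number of resamples whose
#' overlap is at least the observed one (the +1s keep p away from zero).
#' `Z = qnorm(1 - p)` is reported alongside.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `universe`.
#' @param annotations named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all candidate gene ids.
#' @param n_resamples number of random draws B (default 1e5).
#' @param seed integer seed; results are deterministic given it.
#' @return data.frame, one row per term, sorted by `empirical_p`:
#'   `term_id`, `observed_count`, `term_size`, `query_size`,
#'   `universe_size`, `empirical_p`, `z_score`, `n_resamples`, `seed`.
#' @export
empirical_set_enrichment <- function(query, annotations, universe,
                                     n_resamples = 100000L, seed = 1L) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  if (length(setdiff(query, universe)))
    stop("query must be a subset of the universe", call. = FALSE)
  if (length(query) > length(universe))
    stop("query larger than universe", call. = FALSE)
  n <- length(universe)
  q <- length(query)
  terms <- lapply(annotations, function(g) match(intersect(g, universe),
                                                universe))
  qidx <- match(query, universe)
  observed <- vapply(terms, function(t) length(intersect(t, qidx)), 1L)
  # indicator matrix universe x terms; per resample the overlap with term t
  # is the number of drawn indices falling in t
  exceed <- integer(length(terms))
  with_seed(seed, {
    member <- matrix(FALSE, n, length(terms))
    for (k in seq_along(terms)) member[terms[[k]], k] <- TRUE
    chunk <- max(1L, min(n_resamples, ceiling(5e6 / max(q, 1L))))
    done <- 0L
    while (done < n_resamples) {
      b <- min(chunk, n_resamples - done)
      draws <- vapply(seq_len(b), function(i) sample.int(n, q),
                      integer(q))              # q x b index matrix
      for (k in seq_along(terms)) {
        hits <- colSums(matrix(member[draws, k], nrow = q))
        exceed[k] <- exceed[k] + sum(hits >= observed[k])
      }
      done <- done + b
    }
  })
  p <- (exceed + 1) / (n_resamples + 1)
  out <- data.frame(
    term_id = names(annotations) %||% as.character(seq_along(annotations)),
    observed_count = observed,
    term_size = vapply(terms, length, 1L),
    query_size = q, universe_size = n,
    empirical_p = p, z_score = z_from_p(p),
    n_resamples = n_resamples, seed = seed,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$empirical_p, out$term_id), , drop = FALSE]
}

#' Exact hypergeometric tail probability
#'
#' `P(X >= overlap)` for the overlap of a fixed-size query drawn without
#' replacement from the universe with a term of `term_size` genes — the
#' closed-form counterpart of the resampling null, used as its oracle.
#'
#' @param overlap observed overlap count.
#' @param query_size,term_size,universe_size set sizes.
#' @return tail probability in \[0, 1\].
#' @export
hypergeometric_oracle <- function(overlap, query_size, term_size,
                                  universe_size) {
  if (overlap > min(query_size, term_size) ||
      query_size > universe_size || term_size > universe_size ||
      any(c(overlap, query_size, term_size, universe_size) < 0))
    stop("inconsistent sizes for hypergeometric tail", call. = FALSE)
  stats::phyper(overlap - 1, term_size, universe_size - term_size,
                query_size, lower.tail = FALSE)
}

#' Z-score of an enrichment p-value
#'
#' `Z = qnorm(1 - p)`, the inverse standard-normal CDF at `1 - p`. Values
#' outside (0, 1) are clamped to `floor_p` (resp. `1 - floor_p`) with a
#' warning, mirroring the `1/(B+1)` floor of the resampling estimator.
#'
#' @param p numeric vector of p-values.
#' @param floor_p clamp floor for out-of-range values.
#' @return numeric vector of Z-scores.
#' @export
z_from_p <- function(p, floor_p = 1e-6) {
  bad <- p <= 0 | p >= 1
  if (any(bad)) {
    warning("p-value(s) outside (0,1) clamped to [", floor_p, ", ",
            1 - floor_p, "]", call. = FALSE)
    p[p <= 0] <- floor_p
    p[p >= 1] <- 1 - floor_p
  }
  stats::qnorm(1 - p)
}
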