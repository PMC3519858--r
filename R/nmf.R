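# Non-negative matrix factorization of the combined fold-change matrix.
# Signed fold-changes are folded into separate up/down non-negative feature
# rows; factorization is by Frobenius multiplicative updates with random
# restarts and a mandatory seed.

#' Fold a signed matrix into non-negative up/down feature rows
#'
#' Each gene contributes two feature rows: the positive part of its
#' fold-changes (`<gene>|up`) and the positive part of their negation
#' (`<gene>|down`). `up - down` reconstructs the input exactly, so sign
#' information is preserved while the matrix becomes non-negative for NMF.
#'
#' @param combined a `combined_fc_matrix` (or plain numeric matrix with
#'   dimnames).
#' @return non-negative numeric matrix with `2 * n_genes` rows; attributes
#'   `gene` (gene id per row) and `direction` (`"up"`/`"down"` per row).
#' @export
fold_signed_matrix <- function(combined) {
  values <- if (inherits(combined, "combined_fc_matrix")) combined$values
            else combined
  stopifnot_finite(values, "fold-changes")
  up <- pmax(values, 0)
  dn <- pmax(-values, 0)
  rownames(up) <- paste0(rownames(values), "|up")
  rownames(dn) <- paste0(rownames(values), "|down")
  out <- rbind(up, dn)
  attr(out, "gene") <- rep(rownames(values), 2L)
  attr(out, "direction") <- rep(c("up", "down"), each = nrow(values))
  out
}

#' Factorize a non-negative matrix (Frobenius NMF)
#'
#' Multiplicative-update NMF minimizing the Frobenius reconstruction error
#' `||V - W H||_F`. Factors are initialized uniformly at random, scaled by
#' the matrix mean; the best of `n_restarts` initializations is kept.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param V non-negative numeric matrix (features x samples).
#' @param n_clusters number of clusters (rank), `1 <= k <= min(dim(V))`.
#' @param seed integer seed (required; reproducibility is part of the
#'   contract).
#' @param max_iter maximum update iterations per restart.
#' @param tol stop when the relative change of the error drops below this.
#' @param n_restarts random restarts; best final error wins (random init
#'   only).
#' @param init `"nnsvd"` (default): deterministic SVD-based initialization
#'   that seeds pattern-partitioned, parts-like factors (positive/negative
#'   sections of the leading singular vectors); `"random"`: uniform random
#'   scaled by the matrix mean, with `n_restarts` restarts.
#' @return object of class `nmf_fit`: `basis` (W, features x k),
#'   `activation` (H, k x samples), `n_clusters`, `reconstruction_error`,
#'   `error_trace` (per-iteration errors of the winning restart), `seed`,
#'   `n_restarts`, `converged`, `iterations`.
#' @export
factorize_nmf <- function(V, n_clusters, seed, max_iter = 500L,
                          tol = 1e-6, n_restarts = 5L,
                          init = c("nnsvd", "random")) {
  init <- match.arg(init)
  stopifnot_finite(V, "matrix entries")
  if (any(V < 0)) stop("NMF input must be non-negative", call. = FALSE)
  if (n_clusters < 1L || n_clusters > min(dim(V)))
    stop("n_clusters must lie in [1, min(dim(V))]", call. = FALSE)
  if (all(V == 0)) {
    W <- matrix(0, nrow(V), n_clusters,
                dimnames = list(rownames(V),
                                paste0("c", seq_len(n_clusters))))
    H <- matrix(0, n_clusters, ncol(V),
                dimnames = list(colnames(W), colnames(V)))
    return(structure(list(basis = W, activation = H,
                          n_clusters = n_clusters,
                          reconstruction_error = 0,
                          error_trace = 0, seed = seed, n_restarts = 0L,
                          init = init, converged = TRUE, iterations = 0L),
                     class = "nmf_fit"))
  }
  if (init == "nnsvd") {
    start <- nnsvd_start(V, n_clusters)
    best <- nmf_updates(V, start$W, start$H, max_iter, tol)
    n_restarts <- 1L
  } else {
    scale0 <- sqrt(mean(V) / max(n_clusters, 1L))
    best <- NULL
    for (r in seq_len(n_restarts)) {
      start <- with_seed(derive_seed(seed, r), list(
        W = matrix(stats::runif(nrow(V) * n_clusters), nrow(V)) * scale0,
        H = matrix(stats::runif(n_clusters * ncol(V)), n_clusters) * scale0))
      fit <- nmf_updates(V, start$W, start$H, max_iter, tol)
      if (is.null(best) || fit$err < best$err) best <- fit
    }
  }
  structure(list(basis = best$W, activation = best$H,
                 n_clusters = n_clusters,
                 reconstruction_error = best$err,
                 error_trace = best$trace, seed = seed,
                 n_restarts = n_restarts, init = init,
                 converged = best$converged,
                 iterations = length(best$trace)),
            class = "nmf_fit")
}

# Non-negative double SVD start (dense variant): per singular triplet keep
# the positive or negative section with the larger norm product; zeros are
# lifted to mean(V)/100 so multiplicative updates are not locked.
nnsvd_start <- function(V, k) {
  sv <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k)
  H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(k)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn && nup * nvp > 0) {
      W[, j] <- sqrt(sv$d[j] * nup * nvp) * up / nup
      H[j, ] <- sqrt(sv$d[j] * nup * nvp) * vp / nvp
    } else if (nun * nvn > 0) {
      W[, j] <- sqrt(sv$d[j] * nun * nvn) * un / nun
      H[j, ] <- sqrt(sv$d[j] * nun * nvn) * vn / nvn
    }
  }
  lift <- mean(V) / 100
  W[W <= 0] <- lift
  H[H <= 0] <- lift
  list(W = W, H = H)
}

# One multiplicative-update run. eps guards 0/0; a factor entry that reaches
# exactly 0 stays 0 (multiplicative updates preserve zeros).
nmf_updates <- function(V, W, H, max_iter, tol) {
  eps <- .Machine$double.eps
  trace <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- norm(V - W %*% H, "F")
    trace[it] <- err
    if (is.finite(prev) && prev > 0 && abs(prev - err) / prev < tol) {
      converged <- TRUE
      break
    }
    if (err == 0) { converged <- TRUE; break }
    prev <- err
  }
  if (!converged)
    warning(sprintf("NMF did not converge in %d iterations (error %.4g)",
                    max_iter, trace[it]), call. = FALSE)
  # resolve the W/H scale indeterminacy: unit-L2 basis columns, scale into
  # H, so basis and activation values are comparable across factorizations
  d <- sqrt(colSums(W^2))
  pos <- d > 0
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2L, d[pos], "/")
  H[pos, ] <- sweep(H[pos, , drop = FALSE], 1L, d[pos], "*")
  dimnames(W) <- list(rownames(V), paste0("c", seq_len(ncol(W))))
  dimnames(H) <- list(colnames(W), colnames(V))
  list(W = W, H = H, err = trace[it], trace = trace[seq_len(it)],
       converged = converged)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "<nmf_fit> %d features x %d samples, k = %d\n  error %.5g after %d iterations (%sconverged, %d restarts, seed %d)\n",
    nrow(x$basis), ncol(x$activation), x$n_clusters,
    x$reconstruction_error, x$iterations,
    if (x$converged) "" else "NOT ", x$n_restarts, x$seed))
  invisible(x)
}

#' @export
summary.nmf_fit <- function(object, ...) {
  out <- list(
    n_clusters = object$n_clusters,
    reconstruction_error = object$reconstruction_error,
    basis_quantiles = stats::quantile(object$basis),
    activation_quantiles = stats::quantile(object$activation))
  class(out) <- "summary.nmf_fit"
  out
}

#' @export
print.summary.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF with %d clusters, Frobenius error %.5g\n",
              x$n_clusters, x$reconstruction_error))
  cat("basis quantiles:\n"); print(x$basis_quantiles)
  cat("activation quantiles:\n"); print(x$activation_quantiles)
  invisible(x)
}

#' @export
fitted.nmf_fit <- function(object, ...) object$basis %*% object$activation

#' Cluster membership by standardized basis weights
#'
#' Per cluster, the basis column is standardized (z against the column's own
#' mean and standard deviation), converted to an upper-tail normal p-value,
#' and Benjamini-Hochberg adjusted across features within the cluster.
#' Members are the features with adjusted p below `alpha`; a gene's
#' direction is read from whether its up-row or down-row carries the
#' membership. A gene can be a member of several clusters (soft clustering).
#'
#' @param fit an [factorize_nmf()] result on a folded matrix.
#' @param alpha membership significance level (default 0.05).
#' @return data.frame with columns `cluster`, `feature`, `gene`,
#'   `direction`, `basis`, `z`, `p`, `adjusted_p`, one row per (cluster,
#'   member feature). Zero-variance clusters yield no members.
#' @export
compute_membership_pvalues <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "nmf_fit"))
  feats <- rownames(fit$basis)
  gene <- sub("\\|(up|down)$", "", feats)
  direction <- ifelse(grepl("\\|down$", feats), "down", "up")
  out <- vector("list", fit$n_clusters)
  for (j in seq_len(fit$n_clusters)) {
    w <- fit$basis[, j]
    s <- stats::sd(w)
    if (!is.finite(s) || s == 0) next  # flat column: cluster flagged empty
    z <- (w - mean(w)) / s
    p <- stats::pnorm(z, lower.tail = FALSE)
    padj <- stats::p.adjust(p, method = "BH")
    keep <- which(padj < alpha)
    if (!length(keep)) next
    out[[j]] <- data.frame(cluster = j, feature = feats[keep],
                           gene = gene[keep], direction = direction[keep],
                           basis = unname(w[keep]), z = unname(z[keep]),
                           p = unname(p[keep]),
                           adjusted_p = unname(padj[keep]),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cluster = integer(), feature = character(),
                      gene = character(), direction = character(),
                      basis = numeric(), z = numeric(), p = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
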