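#' Non-negative matrix factorization of a binary incidence matrix
#'
#' Factorizes the gene-by-annotation incidence `V` into non-negative gene
#' loadings `W` (genes x k) and annotation loadings `H` (k x annotations)
#' by Lee-Seung multiplicative updates minimizing the generalized
#' Kullback-Leibler divergence
#' `D(V || WH) = sum(V * log(V / WH) - V + WH)` (with `0 * log 0 = 0`).
#' KL suits sparse binary counts; the divergence is non-increasing under the
#' updates, which the implementation exploits for the stopping rule.
#'
#' Among `restarts` random initializations (seeded `seed`, `seed + 1`, ...)
#' the fit with the lowest final divergence is returned. Each restart
#' initializes `W` and `H` with uniform (0, 1] entries scaled so the product
#' matches the data mean, and stops at `max_iter` iterations or when the
#' relative decrease of the divergence falls below `tol`.
#'
#' @param matrix an [annotation_matrix()] with at least one association.
#' @param k number of components, `1 <= k <=` number of genes.
#' @param seed integer seed of the first restart.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative divergence decrease below which iteration stops.
#' @param restarts number of random initializations.
#' @return A list with `W` (genes x k), `H` (k x annotations), `objective`
#'   (final generalized KL divergence), `best_restart` (1-based index of the
#'   winning restart) and `trace` (divergence per iteration of the winner).
#' @export
nmf_factorize <- function(matrix, k, seed = 1L, max_iter = 500L,
                          tol = 1e-6, restarts = 10L) {
  stopifnot(inherits(matrix, "annotation_matrix"))
  V <- unclass(matrix)
  if (sum(V) == 0) stop("all-zero incidence matrix", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(V)) stop("k exceeds the number of genes", call. = FALSE)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .nmf_kl_once(V, k, seed = as.integer(seed) + r - 1L,
                        max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$best_restart <- r
    }
  }
  dimnames(best$W) <- list(rownames(V), NULL)
  dimnames(best$H) <- list(NULL, colnames(V))
  best
}

# one multiplicative-update run from a seeded random initialization
.nmf_kl_once <- function(V, k, seed, max_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-10
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  s <- 2 * sqrt(mean(V) / k)         # mean(WH) ~ k (s/2)^2 = mean(V)
  W <- matrix(s * stats::runif(n * k), n, k)
  H <- matrix(s * stats::runif(k * m), k, m)
  pos <- which(V > 0)
  vpos <- V[pos]
  sumV <- sum(vpos)
  kl <- function(WH) {
    sum(vpos * log(vpos / WH[pos])) - sumV + sum(WH)
  }
  WH <- W %*% H
  obj <- kl(WH)
  trace <- obj
  for (it in seq_len(max_iter)) {
    R <- V / pmax(WH, eps)
    W <- W * (R %*% t(H)) / pmax(matrix(colSums(t(H)), n, k, byrow = TRUE), eps)
    WH <- W %*% H
    R <- V / pmax(WH, eps)
    H <- H * (t(W) %*% R) / pmax(matrix(colSums(W), k, m), eps)
    WH <- W %*% H
    new_obj <- kl(WH)
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol * max(abs(obj), eps)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, trace = trace)
}

#' Hard cluster assignment from gene loadings
#'
#' Each gene goes to the component with maximal loading; ties break toward
#' the lowest component index (a gene with all-zero loadings therefore takes
#' component 1).
#'
#' @param W non-negative gene-by-component loading matrix with gene row names.
#' @return Named integer vector, gene -> cluster index in `1..ncol(W)`.
#' @export
assign_clusters <- function(W) {
  stopifnot(is.matrix(W), all(W >= 0))
  idx <- apply(W, 1L, which.max)   # which.max ties -> first (lowest) index
  a <- as.integer(idx)
  names(a) <- rownames(W)
  a
}

# internal constructor for one clustering solution
new_clustering_level <- function(k_requested, assignment, objective, seed,
                                 n_restarts_used) {
  stopifnot(all(assignment >= 1L), all(assignment <= k_requested))
  structure(list(
    k_requested = as.integer(k_requested),
    assignment = assignment,
    n_nonempty = length(unique(assignment)),
    objective = objective,
    seed = as.integer(seed),
    n_restarts_used = as.integer(n_restarts_used)
  ), class = "clustering_level")
}

#' @export
print.clustering_level <- function(x, ...) {
  cat(sprintf("<clustering_level> k = %d (%d nonempty), %d genes, KL divergence %.4f\n",
              x$k_requested, x$n_nonempty, length(x$assignment), x$objective))
  invisible(x)
}

#' Cluster sizes of a level
#'
#' @param level a `clustering_level`.
#' @return Integer vector of length `k_requested`; empty clusters count 0.
#' @export
cluster_sizes <- function(level) {
  tabulate(level$assignment, nbins = level$k_requested)
}

#' Gene members of one cluster
#'
#' @param level a `clustering_level`.
#' @param index cluster index in `1..k_requested`.
#' @return Character vector of gene identifiers.
#' @export
cluster_members <- function(level, index) {
  names(level$assignment)[level$assignment == index]
}

#' Independent clustering solutions for k = 1..k_max
#'
#' Every level is computed by its own factorization of the full matrix —
#' levels are not refinements of one another, which is what makes the
#' resulting tree non-nested. Level 1 is always the whole gene set in one
#' cluster. Deterministic given `(seed, restarts)`: level k uses restart
#' seeds `seed + (k - 1) * restarts`, ...
#'
#' @inheritParams nmf_factorize
#' @param k_max deepest level, `1 <= k_max <=` number of genes.
#' @return A list of `clustering_level` objects, element k for k clusters.
#' @export
build_levels <- function(matrix, k_max, seed = 1L, max_iter = 500L,
                         tol = 1e-6, restarts = 10L) {
  stopifnot(inherits(matrix, "annotation_matrix"))
  if (k_max < 1L || k_max > nrow(matrix)) {
    stop("k_max must be between 1 and the number of genes", call. = FALSE)
  }
  purrr::map(seq_len(k_max), function(k) {
    level_seed <- as.integer(seed) + (k - 1L) * as.integer(restarts)
    fit <- nmf_factorize(matrix, k, seed = level_seed, max_iter = max_iter,
                         tol = tol, restarts = restarts)
    new_clustering_level(
      k_requested = k,
      assignment = assign_clusters(fit$W),
      objective = fit$objective,
      seed = level_seed,
      n_restarts_used = restarts
    )
  })
}
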