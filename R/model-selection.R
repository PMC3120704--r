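#' Bernoulli log-likelihood of a clustering solution
#'
#' Model: within cluster c, annotation column j is i.i.d. Bernoulli with
#' maximum-likelihood rate `theta(c, j) = (ones in c for j) / |c|`. The
#' log-likelihood sums `ln theta` / `ln(1 - theta)` over all cells, with the
#' degenerate convention `0 * ln 0 = 0` so pure columns contribute zero.
#'
#' @param matrix an [annotation_matrix()].
#' @param assignment named integer vector gene -> cluster covering the
#'   matrix genes (as in a `clustering_level`).
#' @param dimensions optional character vector of annotation identifiers to
#'   score; default all columns.
#' @return The maximized log-likelihood (a non-positive number).
#' @export
bernoulli_loglik <- function(matrix, assignment, dimensions = NULL) {
  V <- .scored_submatrix(matrix, assignment, dimensions)
  ll <- 0
  for (c_idx in unique(assignment)) {
    rows <- which(assignment == c_idx)
    nc <- length(rows)
    n1 <- colSums(V[rows, , drop = FALSE])
    n0 <- nc - n1
    theta <- n1 / nc
    ll <- ll + sum(ifelse(n1 > 0, n1 * log(theta), 0)) +
      sum(ifelse(n0 > 0, n0 * log(1 - theta), 0))
  }
  ll
}

.scored_submatrix <- function(matrix, assignment, dimensions) {
  stopifnot(inherits(matrix, "annotation_matrix"))
  if (!setequal(names(assignment), rownames(matrix))) {
    stop("assignment must cover exactly the matrix genes", call. = FALSE)
  }
  V <- unclass(matrix)[names(assignment), , drop = FALSE]
  if (!is.null(dimensions)) {
    if (length(dimensions) == 0L) stop("empty dimension subset", call. = FALSE)
    if (!all(dimensions %in% colnames(V))) stop("unknown dimensions", call. = FALSE)
    V <- V[, dimensions, drop = FALSE]
  }
  V
}

#' AIC of one clustering level under the per-cluster Bernoulli model
#'
#' `AIC = 2 p - 2 lnL` with `p = (nonempty clusters) x (scored dimensions)`;
#' smaller is better. Empty clusters fit no rates and contribute no
#' parameters.
#'
#' @inheritParams bernoulli_loglik
#' @param level_k the level's requested k (recorded in the score row).
#' @return A one-row tibble: `level_k`, `n_nonempty`, `log_lik`,
#'   `n_parameters`, `aic`.
#' @export
aic_level <- function(matrix, assignment, dimensions = NULL, level_k = NA_integer_) {
  ll <- bernoulli_loglik(matrix, assignment, dimensions)
  n_dims <- if (is.null(dimensions)) ncol(matrix) else length(dimensions)
  n_nonempty <- length(unique(assignment))
  p <- n_nonempty * n_dims
  tibble::tibble(
    level_k = as.integer(level_k),
    n_nonempty = n_nonempty,
    log_lik = ll,
    n_parameters = p,
    aic = 2 * p - 2 * ll
  )
}

#' Per-dimension AIC for every annotation column
#'
#' Restricted to a single column j the model has one rate per nonempty
#' cluster, so `AIC_j = 2 (nonempty clusters) - 2 lnL_j`. Used by the dAIC
#' dimension filter to ask whether a column is distributed non-randomly
#' across the clusters of a solution.
#'
#' @inheritParams bernoulli_loglik
#' @return Named numeric vector of AIC values, one per annotation column.
#' @export
aic_per_dimension <- function(matrix, assignment) {
  V <- .scored_submatrix(matrix, assignment, NULL)
  n_nonempty <- length(unique(assignment))
  ll <- rep(0, ncol(V))
  for (c_idx in unique(assignment)) {
    rows <- which(assignment == c_idx)
    nc <- length(rows)
    n1 <- colSums(V[rows, , drop = FALSE])
    n0 <- nc - n1
    theta <- n1 / nc
    ll <- ll + ifelse(n1 > 0, n1 * log(theta), 0) +
      ifelse(n0 > 0, n0 * log(1 - theta), 0)
  }
  out <- 2 * n_nonempty - 2 * ll
  names(out) <- colnames(V)
  out
}

#' dAIC dimension filter: keep columns that cluster non-randomly
#'
#' A dimension is retained when its per-dimension AIC in at least one
#' multi-cluster solution (k >= `min_k_filter`) beats its AIC in the
#' unclustered gene list (level 1). Randomly distributed columns never beat
#' level 1 — splitting them only adds parameters — so the filter removes
#' them before dAIC scoring, which otherwise tends to be overwhelmed by such
#' columns and to favour one or very few clusters.
#'
#' @param matrix an [annotation_matrix()].
#' @param levels list of `clustering_level` objects including level 1
#'   (as from [build_levels()]).
#' @param min_k_filter smallest k whose solutions may vouch for a dimension;
#'   the default 3 means solutions with more than two clusters.
#' @return Character vector of retained annotation identifiers.
#' @export
daic_dimension_filter <- function(matrix, levels, min_k_filter = 3L) {
  ks <- vapply(levels, function(l) l$k_requested, integer(1))
  if (!1L %in% ks) stop("levels must include the k = 1 solution", call. = FALSE)
  base <- aic_per_dimension(matrix, levels[[which(ks == 1L)[1L]]]$assignment)
  candidate <- levels[ks >= min_k_filter]
  if (length(candidate) == 0L) return(character(0))
  best <- Reduce(pmin, purrr::map(candidate, function(l) {
    aic_per_dimension(matrix, l$assignment)
  }))
  names(base)[best < base]
}

#' dAIC scores: AIC restricted to the retained dimensions
#'
#' The same retained set is used for every level, including the whole gene
#' list as one cluster, so scores are comparable across levels.
#'
#' @inheritParams daic_dimension_filter
#' @param retained_dimensions character vector of annotation identifiers
#'   (from [daic_dimension_filter()]); must be non-empty.
#' @return A tibble with one row per level: `level_k`, `n_nonempty`,
#'   `log_lik`, `n_parameters`, `daic`.
#' @export
daic_scores <- function(matrix, levels, retained_dimensions) {
  if (length(retained_dimensions) == 0L) {
    stop("empty retained dimension set", call. = FALSE)
  }
  purrr::map_dfr(levels, function(l) {
    s <- aic_level(matrix, l$assignment, dimensions = retained_dimensions,
                   level_k = l$k_requested)
    dplyr::rename(s, daic = "aic")
  })
}

#' Select the best level from a score table
#'
#' @param scores tibble with a `level_k` column and the score column named by
#'   `metric`; rows with missing scores are ignored.
#' @param metric score column to minimize (`"aic"` or `"daic"`).
#' @return The `level_k` with the minimal score; ties go to the smaller k.
#' @export
select_best_level <- function(scores, metric = "aic") {
  stopifnot(metric %in% names(scores), "level_k" %in% names(scores))
  ok <- !is.na(scores[[metric]])
  if (!any(ok)) stop("no scored levels", call. = FALSE)
  s <- scores[ok, ]
  s <- s[order(s[[metric]], s$level_k), ]
  as.integer(s$level_k[1L])
}
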