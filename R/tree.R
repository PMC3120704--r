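#' Phi coefficient between two cluster memberships
#'
#' Pearson correlation of the two binary membership indicator vectors over
#' `universe` — the standard correlation between the two binomial membership
#' distributions. When either indicator is constant over the universe (empty
#' cluster, or cluster equal to the whole universe) the correlation is
#' undefined and 0 is returned: such a membership carries no linking
#' information.
#'
#' @param members_a,members_b character vectors of gene identifiers; both
#'   must be subsets of `universe`.
#' @param universe character vector of all genes under consideration.
#' @return The phi coefficient in `[-1, 1]`.
#' @export
membership_phi <- function(members_a, members_b, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(members_a %in% universe) || !all(members_b %in% universe)) {
    stop("cluster members must lie within the universe", call. = FALSE)
  }
  ia <- as.numeric(universe %in% members_a)
  ib <- as.numeric(universe %in% members_b)
  if (stats::sd(ia) == 0 || stats::sd(ib) == 0) return(0)
  stats::cor(ia, ib)
}

#' Link adjacent clustering levels by best phi correlation
#'
#' For every nonempty cluster at level k + 1, adds one edge to the nonempty
#' cluster at level k with which its membership correlates best (ties break
#' toward the lower parent index). Because each child has exactly one
#' parent, the stack of independent partitions becomes a tree-like structure
#' even though the levels are not nested refinements.
#'
#' @param levels list of `clustering_level` objects for k = 1..k_max.
#' @param universe character vector of the clustered genes.
#' @return A tibble of edges: `parent_level`, `parent_cluster`,
#'   `child_level`, `child_cluster`, `phi`.
#' @export
link_adjacent <- function(levels, universe) {
  if (length(levels) < 2L) {
    return(tibble::tibble(parent_level = integer(), parent_cluster = integer(),
                          child_level = integer(), child_cluster = integer(),
                          phi = numeric()))
  }
  purrr::map_dfr(seq_len(length(levels) - 1L), function(i) {
    parent <- levels[[i]]
    child <- levels[[i + 1L]]
    p_idx <- sort(unique(parent$assignment))
    purrr::map_dfr(sort(unique(child$assignment)), function(ci) {
      cm <- cluster_members(child, ci)
      phis <- vapply(p_idx, function(pi) {
        membership_phi(cm, cluster_members(parent, pi), universe)
      }, numeric(1))
      best <- p_idx[which.max(phis)]   # ties -> first = lowest parent index
      tibble::tibble(
        parent_level = parent$k_requested,
        parent_cluster = as.integer(best),
        child_level = child$k_requested,
        child_cluster = as.integer(ci),
        phi = max(phis)
      )
    })
  })
}

#' Build the non-nested cluster tree for one annotation system
#'
#' Runs [build_levels()] for k = 1..`k_max`, scores every level with AIC,
#' applies the dAIC dimension filter and dAIC scoring, links adjacent levels
#' with phi-correlation edges and marks the best AIC and dAIC levels.
#' When the filter retains no dimension, dAIC is undefined and the dAIC best
#' level falls back to the AIC choice.
#'
#' @inheritParams build_levels
#' @param min_k_filter passed to [daic_dimension_filter()].
#' @return An object of class `iea_tree`: list with `matrix`, `levels`,
#'   `edges`, `scores` (per-level `aic` and `daic`), `retained_dimensions`,
#'   `best_aic_level`, `best_daic_level`.
#' @export
build_tree <- function(matrix, k_max, seed = 1L, max_iter = 500L, tol = 1e-6,
                       restarts = 10L, min_k_filter = 3L) {
  levels <- build_levels(matrix, k_max, seed = seed, max_iter = max_iter,
                         tol = tol, restarts = restarts)
  aic <- purrr::map_dfr(levels, function(l) {
    aic_level(matrix, l$assignment, level_k = l$k_requested)
  })
  retained <- daic_dimension_filter(matrix, levels, min_k_filter = min_k_filter)
  scores <- aic
  if (length(retained) > 0L) {
    d <- daic_scores(matrix, levels, retained)
    scores$daic <- d$daic
  } else {
    scores$daic <- NA_real_
  }
  best_aic <- select_best_level(scores, "aic")
  best_daic <- if (all(is.na(scores$daic))) best_aic else select_best_level(scores, "daic")
  structure(list(
    matrix = matrix,
    levels = levels,
    edges = link_adjacent(levels, rownames(matrix)),
    scores = scores,
    retained_dimensions = retained,
    best_aic_level = best_aic,
    best_daic_level = best_daic
  ), class = "iea_tree")
}

#' @export
print.iea_tree <- function(x, ...) {
  cat(sprintf("<iea_tree> system '%s': %d genes, levels 1..%d\n",
              anno_system(x$matrix), nrow(x$matrix), length(x$levels)))
  cat(sprintf("  best level by AIC: %d; by dAIC: %d (%d/%d dimensions retained)\n",
              x$best_aic_level, x$best_daic_level,
              length(x$retained_dimensions), ncol(x$matrix)))
  invisible(x)
}

#' Tidy cluster memberships of a tree
#'
#' @param x an `iea_tree`.
#' @param ... unused.
#' @return A tibble with one row per (level, gene): `level_k`, `cluster`,
#'   `gene`.
#' @exportS3Method generics::tidy
tidy.iea_tree <- function(x, ...) {
  purrr::map_dfr(x$levels, function(l) {
    tibble::tibble(
      level_k = l$k_requested,
      cluster = as.integer(l$assignment),
      gene = names(l$assignment)
    )
  })
}

#' One-row summary of a cluster tree
#'
#' @param x an `iea_tree`.
#' @param ... unused.
#' @return A one-row tibble: system, gene and level counts, retained
#'   dimension count and the best AIC/dAIC levels.
#' @exportS3Method generics::glance
glance.iea_tree <- function(x, ...) {
  tibble::tibble(
    system = anno_system(x$matrix),
    n_genes = nrow(x$matrix),
    n_annotations = ncol(x$matrix),
    k_max = length(x$levels),
    n_retained_dimensions = length(x$retained_dimensions),
    best_aic_level = x$best_aic_level,
    best_daic_level = x$best_daic_level
  )
}
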