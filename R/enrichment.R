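#' One-sided Fisher over-representation p-value
#'
#' Probability that a hypergeometric draw of `n` genes from a population of
#' `N` containing `K_list` annotation carriers yields at least `a` carriers:
#' `P(X >= a)`. Identical to the one-sided (greater) Fisher exact test on the
#' 2x2 table `[a, n - a; K_list - a, N - n - K_list + a]`.
#'
#' @param a carriers observed in the cluster (or list).
#' @param n cluster (or list) size.
#' @param K_list carriers in the background list (or genome).
#' @param N background size.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
fisher_enrichment_p <- function(a, n, K_list, N) {
  ok <- a >= 0 & a <= pmin(n, K_list) & n <= N & K_list <= N &
    a >= n + K_list - N
  if (!all(ok)) stop("invalid 2x2 counts", call. = FALSE)
  stats::phyper(a - 1, K_list, N - K_list, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

.apply_fdr <- function(records, fdr_family) {
  if (nrow(records) == 0L) {
    records$p_fdr <- numeric(0)
    return(records)
  }
  if (fdr_family == "cluster") {
    records <- dplyr::group_by(records, .data$cluster)
    records <- dplyr::mutate(records, p_fdr = bh_fdr(.data$p_raw))
    dplyr::ungroup(records)
  } else {
    dplyr::mutate(records, p_fdr = bh_fdr(.data$p_raw))
  }
}

#' Enrichment of annotations in each cluster versus the gene list
#'
#' For every nonempty cluster of `level` and every annotation of
#' `test_matrix` occurring at least once in that cluster, tests
#' over-representation of the annotation in the cluster against the whole
#' input list with [fisher_enrichment_p()]. The background size `N` is the
#' full list length: list genes without any annotation in the tested system
#' simply count as non-carriers.
#'
#' Mode is `"IEA"` (independent enrichment analysis) when `test_matrix`
#' comes from a different annotation system than the one used to form the
#' clusters, and `"DEA"` otherwise. DEA p-values are descriptive relative
#' enrichment scores only — the clustering variable and the tested variable
#' are the same system, so reading them as tests would be circular — whereas
#' IEA p-values are statistically interpretable.
#'
#' @param level a `clustering_level` whose genes all belong to `genes`.
#' @param test_matrix an [annotation_matrix()] restricted to the list.
#' @param genes character vector: the full input gene list.
#' @param clustered_system label of the system used to build `level`.
#' @param fdr_family `"level"` (default): one BH family per call;
#'   `"cluster"`: BH within each cluster.
#' @return A tibble of enrichment records: `level_k`, `cluster`,
#'   `cluster_size`, `system`, `annotation`, `mode`, `background`, `a`,
#'   `K_list`, `n`, `N`, `p_raw`, `p_fdr`, ordered by cluster then FDR p.
#' @export
enrich_clusters <- function(level, test_matrix, genes, clustered_system,
                            fdr_family = c("level", "cluster")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(test_matrix, "annotation_matrix"))
  genes <- as.character(genes)
  if (!all(names(level$assignment) %in% genes)) {
    stop("clustered genes must belong to the gene list", call. = FALSE)
  }
  if (!all(rownames(test_matrix) %in% genes)) {
    stop("test matrix must be restricted to the gene list", call. = FALSE)
  }
  mode <- if (identical(anno_system(test_matrix), clustered_system)) "DEA" else "IEA"
  N <- length(genes)
  K <- colSums(test_matrix)
  records <- purrr::map_dfr(sort(unique(level$assignment)), function(ci) {
    members <- cluster_members(level, ci)
    present <- intersect(members, rownames(test_matrix))
    a <- if (length(present) > 0L) {
      colSums(unclass(test_matrix)[present, , drop = FALSE])
    } else {
      K * 0
    }
    keep <- a >= 1            # only annotations occurring in the cluster
    if (!any(keep)) return(NULL)
    p <- unname(fisher_enrichment_p(a[keep], length(members), K[keep], N))
    tibble::tibble(
      level_k = level$k_requested,
      cluster = as.integer(ci),
      cluster_size = length(members),
      system = anno_system(test_matrix),
      annotation = names(K)[keep],
      mode = mode,
      background = "list",
      a = as.integer(unname(a[keep])),
      K_list = as.integer(unname(K[keep])),
      n = length(members),
      N = N,
      p_raw = p
    )
  })
  if (nrow(records) == 0L) {
    records <- tibble::tibble(
      level_k = integer(), cluster = integer(), cluster_size = integer(),
      system = character(), annotation = character(), mode = character(),
      background = character(), a = integer(), K_list = integer(),
      n = integer(), N = integer(), p_raw = numeric())
  }
  records <- .apply_fdr(records, fdr_family)
  dplyr::arrange(records, .data$cluster, .data$p_fdr, .data$annotation)
}

#' Enrichment of the gene list versus the genome background
#'
#' The traditional over-representation analysis reported for the tree root:
#' each annotation with at least one occurrence in the list is tested for
#' over-representation in the list against all genes of the genome-wide
#' annotation matrix. List genes absent from the genome matrix are dropped
#' with a message.
#'
#' @param genes character vector: the input gene list.
#' @param genome_matrix genome-wide [annotation_matrix()].
#' @inheritParams enrich_clusters
#' @return An enrichment tibble as in [enrich_clusters()], with
#'   `mode = "LIST_VS_GENOME"`, `background = "genome"`, `level_k = 1` and
#'   `cluster = 1`.
#' @export
enrich_list_vs_genome <- function(genes, genome_matrix,
                                  fdr_family = c("level", "cluster")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(genome_matrix, "annotation_matrix"))
  genes <- as.character(genes)
  eff <- genes[genes %in% rownames(genome_matrix)]
  dropped <- length(genes) - length(eff)
  if (dropped > 0L) {
    message(sprintf("%d list gene(s) absent from the genome background dropped", dropped))
  }
  if (length(eff) == 0L) stop("no list genes in the genome background", call. = FALSE)
  N <- nrow(genome_matrix)
  K <- colSums(genome_matrix)
  a <- colSums(unclass(genome_matrix)[eff, , drop = FALSE])
  keep <- a >= 1
  p <- unname(fisher_enrichment_p(a[keep], length(eff), K[keep], N))
  records <- tibble::tibble(
    level_k = 1L,
    cluster = 1L,
    cluster_size = length(eff),
    system = anno_system(genome_matrix),
    annotation = names(K)[keep],
    mode = "LIST_VS_GENOME",
    background = "genome",
    a = as.integer(a[keep]),
    K_list = as.integer(K[keep]),
    n = length(eff),
    N = N,
    p_raw = p
  )
  records <- .apply_fdr(records, fdr_family)
  dplyr::arrange(records, .data$cluster, .data$p_fdr, .data$annotation)
}

#' Inter-correlation of cluster memberships between two trees
#'
#' Tests every pair of nonempty clusters — one from each of two clustering
#' solutions built on different annotation systems — for membership overlap
#' with the one-sided Fisher exact test on
#' `[|A n B|, |A \\ B|; |B \\ A|, |U \\ (A u B)|]`, BH-corrected across all
#' pairs of the comparison. The universe defaults to the genes clustered in
#' both solutions. Because cluster pairs within a comparison are highly
#' dependent, the correction is conservative and the adjusted values should
#' be read with care.
#'
#' @param level_a,level_b `clustering_level` objects from the two trees.
#' @param universe character vector of genes; default
#'   `intersect(genes of level_a, genes of level_b)`.
#' @return A tibble sorted by `p_fdr`: `cluster_a`, `size_a`, `cluster_b`,
#'   `size_b`, `overlap`, `universe_size`, `p_raw`, `p_fdr`.
#' @export
inter_correlation <- function(level_a, level_b, universe = NULL) {
  if (is.null(universe)) {
    universe <- intersect(names(level_a$assignment), names(level_b$assignment))
  }
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  grid <- tidyr::expand_grid(
    ca = sort(unique(level_a$assignment)),
    cb = sort(unique(level_b$assignment))
  )
  records <- purrr::pmap_dfr(grid, function(ca, cb) {
    A <- intersect(cluster_members(level_a, ca), universe)
    B <- intersect(cluster_members(level_b, cb), universe)
    if (length(A) == 0L || length(B) == 0L) return(NULL)
    ov <- length(intersect(A, B))
    tibble::tibble(
      cluster_a = as.integer(ca), size_a = length(A),
      cluster_b = as.integer(cb), size_b = length(B),
      overlap = ov, universe_size = length(universe),
      p_raw = fisher_enrichment_p(ov, length(A), length(B), length(universe))
    )
  })
  records$p_fdr <- bh_fdr(records$p_raw)
  dplyr::arrange(records, .data$p_fdr, .data$cluster_a, .data$cluster_b)
}
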