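#' Run the full two-system clustering and enrichment pipeline
#'
#' Orchestrates one complete analysis: restrict both annotation systems to
#' the gene list, build a non-nested cluster tree per system (k = 1..k_max,
#' AIC/dAIC level selection, phi-linked levels), test every level's clusters
#' for enrichment of both systems against the list (DEA for the clustering
#' system, IEA for the other), optionally test the list against a genome
#' background, and compute the inter-correlation between the two trees at
#' their best dAIC levels. Results are written to `out_dir` as TSV tables
#' and JSON trees; progress goes to the message stream.
#'
#' @param gene_list character vector of gene identifiers, or a path to a
#'   gene-list file (one identifier per line).
#' @param system_one,system_two [annotation_matrix()] objects, or paths to
#'   association files (`.gmt` parsed as GMT, anything else as two-column
#'   TSV pairs).
#' @param genome_one,genome_two optional genome-background matrices (or
#'   paths) for list-vs-genome enrichment of each system.
#' @param out_dir output directory; created if missing. `NULL` skips file
#'   output and only returns results.
#' @param k_max deepest clustering level.
#' @param seed integer seed governing all randomness of the run.
#' @param restarts,max_iter,tol factorization controls, see [nmf_factorize()].
#' @param min_k_filter dAIC filter threshold, see [daic_dimension_filter()].
#' @param fdr_family BH family policy, see [enrich_clusters()].
#' @return Invisibly, a list: `tree_one`, `tree_two` (`iea_tree`),
#'   `enrichment` (tibble over all levels, modes and systems),
#'   `list_vs_genome` (tibble or NULL), `intercorrelation` (tibble).
#' @export
run_pipeline <- function(gene_list, system_one, system_two,
                         genome_one = NULL, genome_two = NULL,
                         out_dir = NULL, k_max = 8L, seed = 1L,
                         restarts = 10L, max_iter = 500L, tol = 1e-6,
                         min_k_filter = 3L, fdr_family = "level") {
  genes <- if (is.character(gene_list) && length(gene_list) == 1L &&
               file.exists(gene_list)) read_gene_list(gene_list) else as.character(gene_list)
  if (anyDuplicated(genes)) genes <- genes[!duplicated(genes)]
  load_system <- function(x, label) {
    if (inherits(x, "annotation_matrix")) return(x)
    if (grepl("\\.gmt$", x, ignore.case = TRUE)) read_gmt(x, label) else read_pairs_tsv(x, label)
  }
  m1 <- load_system(system_one, "GO")
  m2 <- load_system(system_two, "TF")
  r1 <- restrict_to_list(m1, genes)
  r2 <- restrict_to_list(m2, genes)
  message(sprintf("seed %d; %d list genes; %s: %d genes x %d annotations; %s: %d genes x %d annotations",
                  seed, length(genes),
                  anno_system(r1), nrow(r1), ncol(r1),
                  anno_system(r2), nrow(r2), ncol(r2)))

  k1 <- min(k_max, nrow(r1))
  k2 <- min(k_max, nrow(r2))
  tree_one <- build_tree(r1, k1, seed = seed, max_iter = max_iter, tol = tol,
                         restarts = restarts, min_k_filter = min_k_filter)
  tree_two <- build_tree(r2, k2, seed = seed, max_iter = max_iter, tol = tol,
                         restarts = restarts, min_k_filter = min_k_filter)
  for (tr in list(tree_one, tree_two)) {
    message(sprintf("%s tree: %d/%d dimensions retained by dAIC filter; best AIC level %d, best dAIC level %d",
                    anno_system(tr$matrix), length(tr$retained_dimensions),
                    ncol(tr$matrix), tr$best_aic_level, tr$best_daic_level))
  }

  enrich_tree <- function(tree, own, other) {
    purrr::map_dfr(tree$levels, function(lv) {
      dplyr::bind_rows(
        enrich_clusters(lv, own, genes, anno_system(own), fdr_family = fdr_family),
        enrich_clusters(lv, other, genes, anno_system(own), fdr_family = fdr_family)
      )
    })
  }
  enrichment <- dplyr::bind_rows(
    dplyr::mutate(enrich_tree(tree_one, r1, r2), clustered_system = anno_system(r1)),
    dplyr::mutate(enrich_tree(tree_two, r2, r1), clustered_system = anno_system(r2))
  )

  list_vs_genome <- NULL
  genome_in <- list(genome_one, genome_two)
  for (i in 1:2) {
    if (!is.null(genome_in[[i]])) {
      gm <- load_system(genome_in[[i]], c("GO", "TF")[i])
      list_vs_genome <- dplyr::bind_rows(
        list_vs_genome,
        enrich_list_vs_genome(genes, gm, fdr_family = fdr_family))
    }
  }

  inter <- inter_correlation(tree_one$levels[[tree_one$best_daic_level]],
                             tree_two$levels[[tree_two$best_daic_level]])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tree_json(tree_one, file.path(out_dir, "tree_one.json"))
    write_tree_json(tree_two, file.path(out_dir, "tree_two.json"))
    by_sys <- split(enrichment, enrichment$clustered_system)
    for (s in names(by_sys)) {
      write_enrichment_tsv(by_sys[[s]],
                           file.path(out_dir, sprintf("enrichment_%s_tree.tsv", s)))
    }
    if (!is.null(list_vs_genome)) {
      write_enrichment_tsv(list_vs_genome, file.path(out_dir, "list_vs_genome.tsv"))
    }
    .write_plain_tsv(inter, file.path(out_dir, "intercorrelation.tsv"))
    message("results written to ", out_dir)
  }

  invisible(list(tree_one = tree_one, tree_two = tree_two,
                 enrichment = enrichment, list_vs_genome = list_vs_genome,
                 intercorrelation = inter))
}

.write_plain_tsv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(x) {
      if (is.double(x)) sprintf("%.14e", x) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
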