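#' Read a gene list from a plain-text file
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' skipped; surrounding whitespace is trimmed and case is preserved.
#' Duplicates are collapsed keeping the first occurrence, with a message.
#'
#' @param path path to the gene-list file.
#' @return Character vector of unique gene identifiers in file order.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list: ", path, call. = FALSE)
  if (anyDuplicated(lines)) {
    message(sprintf("%d duplicate identifier(s) collapsed in %s",
                    sum(duplicated(lines)), path))
    lines <- lines[!duplicated(lines)]
  }
  lines
}

# shared: non-comment, non-blank lines plus their original line numbers
.content_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")
  list(lines = raw[keep], lineno = which(keep))
}

#' Read gene-annotation associations from a two-column TSV file
#'
#' Each non-comment line is `gene<TAB>annotation`. Repeated pairs are
#' idempotent: the incidence cell is set to 1 once.
#'
#' @param path path to the TSV file.
#' @param system annotation-system label for the resulting matrix.
#' @return An [annotation_matrix()] over the union of genes and annotations seen.
#' @export
read_pairs_tsv <- function(path, system) {
  cl <- .content_lines(path)
  if (length(cl$lines) == 0L) stop("no association lines in ", path, call. = FALSE)
  fields <- strsplit(cl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated fields, got %d",
                 cl$lineno[bad], path, nf[bad]), call. = FALSE)
  }
  df <- tibble::tibble(
    gene = trimws(vapply(fields, `[[`, "", 1L)),
    annotation = trimws(vapply(fields, `[[`, "", 2L))
  )
  as_annotation_matrix(df, system)
}

#' Read gene sets in GMT format as an annotation matrix
#'
#' Standard GMT: `setname<TAB>description<TAB>gene1<TAB>gene2...`. Each set
#' becomes one annotation column; membership is incidence 1.
#'
#' @inheritParams read_pairs_tsv
#' @return An [annotation_matrix()] with one column per gene set.
#' @export
read_gmt <- function(path, system) {
  cl <- .content_lines(path)
  if (length(cl$lines) == 0L) stop("no gene sets in ", path, call. = FALSE)
  fields <- strsplit(cl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop(sprintf("malformed GMT line %d in %s: expected set, description and >=1 gene",
                 cl$lineno[bad], path), call. = FALSE)
  }
  df <- purrr::map_dfr(fields, function(f) {
    tibble::tibble(gene = trimws(f[-(1:2)]), annotation = trimws(f[[1L]]))
  })
  as_annotation_matrix(df, system)
}

#' Write an enrichment table to TSV
#'
#' Writes one row per enrichment record with deterministic ordering
#' (level, cluster, mode, FDR p ascending, annotation id). P-values below
#' 1e-4 are printed in scientific notation, larger ones in plain decimal;
#' both round-trip through [read_enrichment_tsv()] exactly at the printed
#' precision of 15 significant digits.
#'
#' @param records enrichment tibble as returned by [enrich_clusters()] /
#'   [enrich_list_vs_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(records, path) {
  cols <- c("level_k", "cluster", "cluster_size", "system", "annotation",
            "mode", "background", "a", "K_list", "n", "N", "p_raw", "p_fdr")
  stopifnot(all(cols %in% names(records)))
  records <- dplyr::arrange(records, .data$level_k, .data$cluster, .data$mode,
                            .data$p_fdr, .data$annotation)
  fmt_p <- function(p) {
    ifelse(p < 1e-4, sprintf("%.14e", p), sprintf("%.15f", p))
  }
  body <- records
  body$p_raw <- fmt_p(records$p_raw)
  body$p_fdr <- fmt_p(records$p_fdr)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(body) > 0L) {
    lines <- do.call(paste, c(unname(as.list(body[cols])), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_enrichment_tsv
#' @return for `read_enrichment_tsv`, the enrichment tibble.
#' @export
read_enrichment_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(
                            level_k = "integer", cluster = "integer",
                            cluster_size = "integer", system = "character",
                            annotation = "character", mode = "character",
                            background = "character", a = "integer",
                            K_list = "integer", n = "integer", N = "integer",
                            p_raw = "numeric", p_fdr = "numeric"))
  tibble::as_tibble(df)
}

#' Serialize a cluster tree to JSON
#'
#' The serialization contains every level with its cluster memberships,
#' every adjacent-level edge with its phi correlation, the per-level AIC and
#' dAIC scores and the selected best levels; [read_tree_json()] restores an
#' identical tree.
#'
#' @param tree an `iea_tree` as built by [build_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "iea_tree"))
  if (length(tree$levels) == 0L) stop("empty tree", call. = FALSE)
  obj <- list(
    system = anno_system(tree$matrix),
    genes = rownames(tree$matrix),
    levels = purrr::map(tree$levels, function(lv) {
      list(
        k = lv$k_requested,
        objective = lv$objective,
        seed = lv$seed,
        n_restarts_used = lv$n_restarts_used,
        clusters = purrr::map(seq_len(lv$k_requested), function(ci) {
          list(index = ci, genes = names(lv$assignment)[lv$assignment == ci])
        })
      )
    }),
    edges = tree$edges,
    scores = tree$scores,
    retained_dimensions = tree$retained_dimensions,
    best_aic_level = tree$best_aic_level,
    best_daic_level = tree$best_daic_level
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @param matrix the `annotation_matrix` the tree was built from (memberships
#'   and scores are stored in the JSON; the incidence itself is not, so the
#'   caller re-supplies it).
#' @rdname write_tree_json
#' @export
read_tree_json <- function(path, matrix) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  levels <- purrr::map(obj$levels, function(lv) {
    assignment <- integer(0)
    for (cl in lv$clusters) {
      g <- unlist(cl$genes, use.names = FALSE)
      if (length(g) > 0L) {
        a <- rep.int(as.integer(cl$index), length(g))
        names(a) <- g
        assignment <- c(assignment, a)
      }
    }
    assignment <- assignment[match(unlist(obj$genes), names(assignment))]
    new_clustering_level(
      k_requested = as.integer(lv$k),
      assignment = assignment,
      objective = as.numeric(lv$objective),
      seed = as.integer(lv$seed),
      n_restarts_used = as.integer(lv$n_restarts_used)
    )
  })
  edges <- dplyr::bind_rows(purrr::map(obj$edges, tibble::as_tibble))
  scores <- dplyr::bind_rows(purrr::map(obj$scores, function(s) {
    tibble::as_tibble(purrr::map(s, function(v) if (is.null(v)) NA else v))
  }))
  structure(list(
    matrix = matrix,
    levels = levels,
    edges = edges,
    scores = scores,
    retained_dimensions = unlist(obj$retained_dimensions, use.names = FALSE),
    best_aic_level = as.integer(obj$best_aic_level),
    best_daic_level = as.integer(obj$best_daic_level)
  ), class = "iea_tree")
}
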