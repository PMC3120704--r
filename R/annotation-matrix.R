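#' Binary gene-by-annotation incidence matrix
#'
#' An `annotation_matrix` holds the 0/1 incidence structure of one annotation
#' system (for example Gene Ontology terms, or transcription-factor target
#' annotations): rows are genes, columns are annotation identifiers, and a cell
#' value of one records that the gene carries the annotation. All clustering
#' and enrichment in the package operates on this container.
#'
#' @param x for `annotation_matrix()`, a numeric matrix of 0/1 values with
#'   gene row names and annotation column names; for `as_annotation_matrix()`,
#'   a data frame of gene-annotation pairs.
#' @param system single string naming the annotation system (e.g. `"GO"`,
#'   `"TF"`). Used to label enrichment output and to decide DEA vs IEA mode.
#'
#' @return An object of class `annotation_matrix`: the incidence matrix with
#'   a `system` attribute. `anno_genes()` and `anno_terms()` return the row
#'   and column identifier vectors; `anno_system()` the system label.
#'
#' @examples
#' m <- matrix(c(1, 1, 1, 0), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("A", "B")))
#' am <- annotation_matrix(m, "GO")
#' anno_genes(am)
#' @export
annotation_matrix <- function(x, system) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("incidence matrix needs gene row names and annotation column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate annotation identifiers", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("incidence values must be 0 or 1", call. = FALSE)
  if (!is.character(system) || length(system) != 1L || !nzchar(system)) {
    stop("`system` must be a single non-empty string", call. = FALSE)
  }
  storage.mode(x) <- "double"
  structure(x, system = system, class = c("annotation_matrix", "matrix", "array"))
}

#' @param gene,annotation column names in `x` holding gene and annotation
#'   identifiers (for the data-frame constructor).
#' @rdname annotation_matrix
#' @export
as_annotation_matrix <- function(x, system, gene = "gene", annotation = "annotation") {
  stopifnot(is.data.frame(x))
  g <- as.character(x[[gene]])
  a <- as.character(x[[annotation]])
  if (length(g) == 0L) stop("no gene-annotation pairs", call. = FALSE)
  genes <- unique(g)
  terms <- unique(a)
  m <- matrix(0, length(genes), length(terms), dimnames = list(genes, terms))
  m[cbind(match(g, genes), match(a, terms))] <- 1
  annotation_matrix(m, system)
}

#' @rdname annotation_matrix
#' @export
anno_system <- function(x) attr(x, "system")

#' @rdname annotation_matrix
#' @export
anno_genes <- function(x) rownames(x)

#' @rdname annotation_matrix
#' @export
anno_terms <- function(x) colnames(x)

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("<annotation_matrix> system '%s': %d genes x %d annotations, %d associations\n",
              anno_system(x), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Tidy gene-annotation pairs from an incidence matrix
#'
#' @param x an `annotation_matrix`.
#' @param ... unused.
#' @return A tibble with columns `gene`, `annotation`, one row per association.
#' @exportS3Method generics::tidy
tidy.annotation_matrix <- function(x, ...) {
  idx <- which(x == 1, arr.ind = TRUE)
  out <- tibble::tibble(
    gene = rownames(x)[idx[, 1]],
    annotation = colnames(x)[idx[, 2]]
  )
  dplyr::arrange(out, match(.data$gene, rownames(x)), match(.data$annotation, colnames(x)))
}

#' Restrict an annotation matrix to the genes of a list
#'
#' Keeps only rows for genes present in `genes`; genes of the list that carry
#' no annotation in this system are dropped (with a message naming the count)
#' since an all-zero row gives the factorization no signal. Annotation columns
#' that lose all their members are removed.
#'
#' @param matrix an `annotation_matrix`.
#' @param genes character vector of gene identifiers (the analysis list).
#' @return An `annotation_matrix` over `intersect(genes, anno_genes(matrix))`,
#'   row order following `genes`.
#' @export
restrict_to_list <- function(matrix, genes) {
  stopifnot(inherits(matrix, "annotation_matrix"))
  genes <- as.character(genes)
  keep <- genes[genes %in% rownames(matrix)]
  missing <- setdiff(genes, keep)
  if (length(missing) > 0L) {
    message(sprintf("%d gene(s) of the list have no %s annotation and are excluded: %s",
                    length(missing), anno_system(matrix),
                    paste(utils::head(missing, 5L), collapse = ", ")))
  }
  if (length(keep) == 0L) {
    stop(sprintf("no genes of the list are annotated in system '%s'",
                 anno_system(matrix)), call. = FALSE)
  }
  m <- unclass(matrix)[keep, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) == 0L) stop("no annotations remain after restriction", call. = FALSE)
  annotation_matrix(m, anno_system(matrix))
}
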