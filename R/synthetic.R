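#' Generate coupled binary annotation systems with a planted partition
#'
#' Emulates the two annotation systems an analysis consumes — one playing
#' the functional-ontology role, one the transcription-factor-target role —
#' as binary incidence matrices over a common gene list with a planted
#' ground-truth partition. Each cluster owns `signal_dims` disjoint signal
#' columns per system; gene g carries a 1 in its own cluster's signal
#' columns with probability `p_in` and in any other signal or background
#' column with probability `p_out`. With probability `coupling` (drawn once
#' per dataset) the second system's signal block follows the same planted
#' partition; otherwise it follows an independent random partition with the
#' same cluster sizes, which makes the second system uninformative about the
#' first — the null regime for independent-enrichment error-control studies.
#'
#' @param n_genes number of genes (`>= k_true`).
#' @param k_true number of planted clusters.
#' @param signal_dims signal annotation columns owned by each cluster, per
#'   system.
#' @param background_dims extra unstructured columns per system, i.i.d.
#'   Bernoulli(`p_out`).
#' @param p_in within-cluster signal probability.
#' @param p_out background probability.
#' @param coupling probability that system two shares the planted partition.
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @return A list of class `synthetic_dataset`: `partition` (named integer
#'   vector gene -> true cluster), `partition_two` (the partition actually
#'   used by system two), `coupled` (logical), `system_one`, `system_two`
#'   ([annotation_matrix()] objects, systems `"GO"` and `"TF"`), and
#'   `parameters`.
#' @export
generate_annotation_systems <- function(n_genes = 200L, k_true = 4L,
                                        signal_dims = 3L, background_dims = 20L,
                                        p_in = 0.9, p_out = 0.05,
                                        coupling = 1, seed = 1L) {
  if (n_genes < k_true || k_true < 1L) stop("need n_genes >= k_true >= 1", call. = FALSE)
  for (pr in c(p_in, p_out, coupling)) {
    if (!is.finite(pr) || pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  genes <- sprintf("g%04d", seq_len(n_genes))
  partition <- rep_len(seq_len(k_true), n_genes)    # balanced planted clusters
  names(partition) <- genes

  coupled <- stats::runif(1) < coupling
  partition_two <- if (coupled) partition else {
    p2 <- partition[sample.int(n_genes)]            # same sizes, shuffled genes
    names(p2) <- genes
    p2
  }

  sim_system <- function(part, prefix, system) {
    m_sig <- k_true * signal_dims
    cols <- c(sprintf("%s_sig_c%d_%d", prefix,
                      rep(seq_len(k_true), each = signal_dims),
                      rep(seq_len(signal_dims), k_true)),
              if (background_dims > 0L) sprintf("%s_bg_%d", prefix, seq_len(background_dims)))
    owner <- c(rep(seq_len(k_true), each = signal_dims),
               rep(NA_integer_, background_dims))
    prob <- matrix(p_out, n_genes, m_sig + background_dims)
    for (j in seq_len(m_sig)) prob[part == owner[j], j] <- p_in
    m <- matrix(as.numeric(stats::runif(length(prob)) < prob), n_genes,
                m_sig + background_dims, dimnames = list(genes, cols))
    annotation_matrix(m, system)
  }

  structure(list(
    partition = partition,
    partition_two = partition_two,
    coupled = coupled,
    system_one = sim_system(partition, "A", "GO"),
    system_two = sim_system(partition_two, "B", "TF"),
    parameters = list(n_genes = n_genes, k_true = k_true,
                      signal_dims = signal_dims, background_dims = background_dims,
                      p_in = p_in, p_out = p_out, coupling = coupling,
                      seed = as.integer(seed))
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<synthetic_dataset> %d genes, %d planted clusters, coupling %.2f (%s)\n",
              p$n_genes, p$k_true, p$coupling,
              if (x$coupled) "coupled" else "decoupled"))
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits `genes.txt` (the gene list), `system_one.tsv` / `system_two.tsv`
#' (two-column gene-annotation pairs), `truth.tsv` (planted partition) and
#' `parameters.json` into `dir`, so a generated dataset can drive the
#' end-to-end pipeline from files.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(names(dataset$partition), file.path(dir, "genes.txt"))
  write_pairs <- function(m, path) {
    df <- tidy.annotation_matrix(m)
    writeLines(paste(df$gene, df$annotation, sep = "\t"), path)
  }
  write_pairs(dataset$system_one, file.path(dir, "system_one.tsv"))
  write_pairs(dataset$system_two, file.path(dir, "system_two.tsv"))
  writeLines(paste(names(dataset$partition), dataset$partition, sep = "\t"),
             file.path(dir, "truth.tsv"))
  jsonlite::write_json(c(dataset$parameters, list(coupled = dataset$coupled)),
                       file.path(dir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same gene set
#' (permutation model); 1 for identical partitions, about 0 at chance.
#'
#' @param partition_a,partition_b named vectors gene -> cluster label over
#'   the same genes.
#' @return The adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(partition_a, partition_b) {
  if (is.null(names(partition_a)) || is.null(names(partition_b)) ||
      !setequal(names(partition_a), names(partition_b))) {
    stop("partitions must be named and cover the same gene set", call. = FALSE)
  }
  b <- partition_b[names(partition_a)]
  mclust::adjustedRandIndex(as.vector(partition_a), as.vector(b))
}
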