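test_that("hypergeometric tail p-values match closed forms", {
  expect_equal(fisher_enrichment_p(0, 10, 5, 100), 1)
  expect_equal(fisher_enrichment_p(5, 5, 5, 10), 1 / choose(10, 5))
  expect_error(fisher_enrichment_p(6, 5, 5, 10), "invalid")
  expect_error(fisher_enrichment_p(2, 5, 20, 10), "invalid")
})

test_that("tail probabilities agree with enumeration and with fisher.test", {
  set.seed(17)
  for (i in 1:200) {
    N <- sample(2:40, 1)
    n <- sample.int(N, 1)
    K <- sample.int(N, 1)
    a_range <- max(0, n + K - N):min(n, K)
    a <- a_range[sample.int(length(a_range), 1)]
    p <- fisher_enrichment_p(a, n, K, N)
    expect_equal(p, hyper_tail_oracle(a, n, K, N), tolerance = 1e-12)
  }
  # dual route: one-sided Fisher on the explicit 2x2 table
  for (case in list(c(8, 26, 32, 691), c(3, 10, 6, 50), c(5, 5, 5, 10))) {
    a <- case[1]; n <- case[2]; K <- case[3]; N <- case[4]
    tab <- matrix(c(a, n - a, K - a, N - n - K + a), 2, 2, byrow = TRUE)
    expect_equal(fisher_enrichment_p(a, n, K, N),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("cluster enrichment builds the 2x2 counts against the whole list", {
  # 6-gene list, cluster 1 = {g01,g02,g03} carries A1..A3, cluster 2 the B's
  m <- block_matrix(3, 3, system = "TF")
  genes <- anno_genes(m)
  lv <- make_level(stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), genes))
  rec <- enrich_clusters(lv, m, genes, "GO")
  expect_true(all(rec$mode == "IEA"))
  # occurrence filter: cluster 1 records only the A annotations
  expect_setequal(rec$annotation[rec$cluster == 1], c("A1", "A2", "A3"))
  r <- rec[rec$cluster == 1 & rec$annotation == "A1", ]
  expect_equal(r$a, 3L); expect_equal(r$n, 6L %/% 2L)
  expect_equal(r$K_list, 3L); expect_equal(r$N, 6L)
  expect_equal(r$p_raw, 1 / choose(6, 3))
  # FDR family = all records of the call
  expect_equal(rec$p_fdr, bh_stepup_oracle(rec$p_raw))
  # DEA mode when the tested system is the clustering system
  expect_true(all(enrich_clusters(lv, m, genes, "TF")$mode == "DEA"))
  expect_error(enrich_clusters(lv, m, genes[-1], "GO"), "belong to the gene list")
})

test_that("per-cluster FDR families adjust within each cluster", {
  m <- block_matrix(4, 4, system = "TF")
  genes <- anno_genes(m)
  lv <- make_level(stats::setNames(rep(1:2, each = 4), genes))
  rec <- enrich_clusters(lv, m, genes, "GO", fdr_family = "cluster")
  for (ci in unique(rec$cluster)) {
    sub <- rec[rec$cluster == ci, ]
    expect_equal(sub$p_fdr, bh_stepup_oracle(sub$p_raw))
  }
})

test_that("list-vs-genome enrichment uses the genome background", {
  set.seed(29)
  genome_genes <- sprintf("g%03d", 1:100)
  V <- matrix(rbinom(300, 1, 0.2), 100, 3,
              dimnames = list(genome_genes, c("X", "Y", "Z")))
  V[, "Z"] <- 0
  V[1:10, "Z"] <- 1                      # list holds all 10 carriers of Z
  gm <- annotation_matrix(V, "GO")
  lst <- genome_genes[1:10]
  rec <- enrich_list_vs_genome(lst, gm)
  z <- rec[rec$annotation == "Z", ]
  expect_equal(z$a, 10L); expect_equal(z$K_list, 10L); expect_equal(z$N, 100L)
  expect_equal(z$p_raw, hyper_tail_oracle(10, 10, 10, 100))
  expect_true(all(rec$a >= 1))           # zero-occurrence annotations excluded
  # list equal to genome: no enrichment possible
  rec_all <- enrich_list_vs_genome(genome_genes, gm)
  expect_true(all(rec_all$p_raw == 1))
  expect_message(enrich_list_vs_genome(c(lst, "absent"), gm), "dropped")
  expect_error(enrich_list_vs_genome("absent", gm), "no list genes")
})

test_that("inter-correlation ranks identical clusters first", {
  u <- paste0("g", 1:20)
  part <- stats::setNames(rep(1:4, each = 5), u)
  la <- make_level(part)
  lb <- make_level(part)
  ic <- inter_correlation(la, lb, u)
  expect_equal(nrow(ic), 16)
  self <- ic[ic$cluster_a == ic$cluster_b, ]
  expect_true(all(self$overlap == 5))
  expect_equal(self$p_raw, rep(1 / choose(20, 5), 4))
  for (ca in 1:4) {
    row_p <- ic$p_raw[ic$cluster_a == ca]
    expect_equal(min(row_p), ic$p_raw[ic$cluster_a == ca & ic$cluster_b == ca])
  }
  expect_error(inter_correlation(la, lb, character(0)), "empty universe")
  expect_true(!is.unsorted(ic$p_fdr))
})

test_that("independent random partitions rarely reach inter-correlation significance", {
  set.seed(37)
  u <- sprintf("g%03d", 1:100)
  frac <- replicate(20, {
    la <- make_level(stats::setNames(sample(rep(1:4, each = 25)), u))
    lb <- make_level(stats::setNames(sample(rep(1:4, each = 25)), u))
    ic <- inter_correlation(la, lb, u)
    mean(ic$p_fdr < 0.05)
  })
  expect_lte(mean(frac), 0.06)
})

test_that("worked forskolin example: cluster counts give raw p below printed FDR values", {
  # 691-gene list, 26-gene cluster: 8/26 HES-1 targets vs 32/691,
  # 15/26 AhR targets vs 123/691
  expect_lte(fisher_enrichment_p(8, 26, 32, 691), 0.02)
  expect_lte(fisher_enrichment_p(15, 26, 123, 691), 0.029)
})
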