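two_gene_matrix <- function(col) {
  annotation_matrix(matrix(col, length(col), 1,
                           dimnames = list(paste0("g", seq_along(col)), "A")),
                    "GO")
}

test_that("Bernoulli log-likelihood matches closed forms and the cell-wise oracle", {
  one <- rep(1L, 2)
  names(one) <- c("g1", "g2")
  expect_equal(bernoulli_loglik(two_gene_matrix(c(1, 1)), one), 0)          # theta = 1
  expect_equal(bernoulli_loglik(two_gene_matrix(c(1, 0)), one), 2 * log(0.5))

  set.seed(42)
  V <- matrix(rbinom(18, 1, 0.5), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("A", 1:3)))
  m <- annotation_matrix(V, "GO")
  assign <- c(1L, 1L, 1L, 2L, 2L, 2L)
  names(assign) <- rownames(V)
  expect_equal(bernoulli_loglik(m, assign), loglik_cellwise_oracle(V, assign))
  expect_lte(bernoulli_loglik(m, assign), 0)
  expect_error(bernoulli_loglik(m, assign, character(0)), "empty dimension")
})

test_that("AIC equals 2p - 2lnL with parameters only for nonempty clusters", {
  z <- annotation_matrix(matrix(0, 5, 3, dimnames = list(paste0("g", 1:5),
                                                         paste0("A", 1:3))), "GO")
  a1 <- rep(1L, 5); names(a1) <- rownames(z)
  s <- aic_level(z, a1, level_k = 1)
  expect_equal(s$log_lik, 0)
  expect_equal(s$aic, 6)              # 3 zero-rate parameters, lnL = 0

  one <- c(g1 = 1L, g2 = 1L)
  s2 <- aic_level(two_gene_matrix(c(1, 0)), one, level_k = 1)
  expect_equal(s2$aic, 2 - 2 * (2 * log(0.5)))

  # empty clusters carry no parameters
  m <- block_matrix(3, 3)
  sparse <- rep(1L, 6); names(sparse) <- anno_genes(m)
  s3 <- aic_level(m, sparse, level_k = 5)   # k = 5 requested, 1 nonempty
  expect_equal(s3$n_parameters, 1 * ncol(m))
  # identity recheck on every emitted score
  expect_equal(s3$aic, 2 * s3$n_parameters - 2 * s3$log_lik)
})

test_that("splitting on the true structure improves AIC over one cluster", {
  m <- block_matrix(5, 5)
  truth <- c(rep(1L, 5), rep(2L, 5)); names(truth) <- anno_genes(m)
  whole <- rep(1L, 10); names(whole) <- anno_genes(m)
  expect_lt(aic_level(m, truth)$aic, aic_level(m, whole)$aic)
})

test_that("log-likelihood never decreases when clusters only split", {
  set.seed(7)
  V <- matrix(rbinom(80, 1, 0.4), 20, 4,
              dimnames = list(paste0("g", 1:20), paste0("A", 1:4)))
  m <- annotation_matrix(V, "GO")
  coarse <- rep(1:2, each = 10); names(coarse) <- rownames(V)
  fine <- coarse
  fine[1:5] <- 3L                      # split cluster 1
  expect_gte(bernoulli_loglik(m, fine), bernoulli_loglik(m, coarse))
})

test_that("per-dimension AIC has the closed-form values", {
  z <- annotation_matrix(matrix(0, 6, 1, dimnames = list(paste0("g", 1:6), "A")), "GO")
  a1 <- rep(1L, 6); names(a1) <- rownames(z)
  a3 <- rep(1:3, each = 2); names(a3) <- rownames(z)
  expect_equal(unname(aic_per_dimension(z, a1)), 2)
  expect_equal(unname(aic_per_dimension(z, a3)), 6)

  # column perfectly split by a 2-partition: AIC(k=2) = 4 beats k = 1
  split_col <- two_gene_matrix(c(1, 1, 1, 0, 0, 0))
  a2 <- rep(1:2, each = 3); names(a2) <- anno_genes(split_col)
  a1b <- rep(1L, 6); names(a1b) <- anno_genes(split_col)
  expect_equal(unname(aic_per_dimension(split_col, a2)), 4)
  expect_equal(unname(aic_per_dimension(split_col, a1b)), 2 - 2 * 6 * log(0.5))
  expect_lt(4, 2 - 2 * 6 * log(0.5))
})

test_that("the dAIC filter keeps structured columns and discards flat ones", {
  m <- block_matrix(6, 6)
  V <- cbind(unclass(m), flat = 0)     # an all-zero column can never improve
  m2 <- annotation_matrix(V, "GO")
  truth <- c(rep(1L, 6), rep(2L, 6)); names(truth) <- rownames(V)
  lv <- list(make_level(stats::setNames(rep(1L, 12), rownames(V)), 1),
             make_level(truth, 3))     # a 3-requested level with 2 nonempty
  kept <- daic_dimension_filter(m2, lv, min_k_filter = 3)
  expect_false("flat" %in% kept)
  expect_true(all(c("A1", "B1") %in% kept))
  expect_error(daic_dimension_filter(m2, lv[2]), "k = 1")
})

test_that("dAIC equals AIC when every dimension is retained", {
  d <- generate_annotation_systems(n_genes = 40, k_true = 2, seed = 9)
  m <- d$system_one
  lv <- build_levels(m, 3, seed = 9, restarts = 3)
  daic <- daic_scores(m, lv, anno_terms(m))
  aic <- purrr::map_dfr(lv, function(l) aic_level(m, l$assignment, level_k = l$k_requested))
  expect_equal(daic$daic, aic$aic)
  expect_error(daic_scores(m, lv, character(0)), "empty retained")
})

test_that("best-level selection minimizes with ties to the smaller k", {
  sc <- tibble::tibble(level_k = 1:3, aic = c(10, 5, 7))
  expect_identical(select_best_level(sc, "aic"), 2L)
  expect_identical(select_best_level(tibble::tibble(level_k = 1:2, aic = c(5, 5)), "aic"), 1L)
  expect_identical(select_best_level(tibble::tibble(level_k = 4L, daic = 1), "daic"), 4L)
})
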