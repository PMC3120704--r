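# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the hypergeometric tail is summed from binomial
# coefficients, BH is a literal step-up, and the Rand index is counted over
# gene pairs.

hyper_tail_oracle <- function(a, n, K, N) {
  x <- a:min(n, K)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

ari_pair_oracle <- function(a, b) {
  b <- b[names(a)]
  pairs <- utils::combn(length(a), 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  np <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / np
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) return(0)
  (n11 - expected) / (maxidx - expected)
}

# cell-by-cell Bernoulli log-likelihood, no vectorized shortcuts
loglik_cellwise_oracle <- function(V, assignment) {
  ll <- 0
  for (ci in unique(assignment)) {
    rows <- which(assignment == ci)
    for (j in seq_len(ncol(V))) {
      theta <- mean(V[rows, j])
      for (i in rows) {
        obs <- V[i, j]
        contrib <- if (obs == 1) {
          if (theta > 0) log(theta) else 0
        } else {
          if (theta < 1) log(1 - theta) else 0
        }
        ll <- ll + contrib
      }
    }
  }
  ll
}

# two perfect disjoint blocks: genes 1..n1 carry annotations A*, rest carry B*
block_matrix <- function(n1 = 5, n2 = 5, m1 = 3, m2 = 3, system = "GO") {
  genes <- sprintf("g%02d", seq_len(n1 + n2))
  cols <- c(sprintf("A%d", seq_len(m1)), sprintf("B%d", seq_len(m2)))
  m <- matrix(0, n1 + n2, m1 + m2, dimnames = list(genes, cols))
  m[seq_len(n1), seq_len(m1)] <- 1
  m[n1 + seq_len(n2), m1 + seq_len(m2)] <- 1
  annotation_matrix(m, system)
}

make_level <- function(assignment, k = max(assignment)) {
  ieaclust:::new_clustering_level(k_requested = k, assignment = assignment,
                                  objective = 0, seed = 0L, n_restarts_used = 1L)
}
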