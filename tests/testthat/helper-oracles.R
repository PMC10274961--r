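# Independent oracles used across the suite. Each is deliberately naive
# (dense linear algebra, exhaustive enumeration, grid search) and shares no
# code with the package implementation it checks.

# Brute-force upper-tail hypergeometric: enumerate every size-n draw from a
# universe with K annotated elements and count draws overlapping >= k.
hyper_enum_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the annotated ones
  mean(hits >= k)
}

# Dense closed-form RWR: p = r (I - (1-r) W)^(-1) e with column-stochastic W
# built from a symmetric weight matrix by plain base R.
rwr_dense_oracle <- function(adj, seed_idx, r) {
  W <- sweep(adj, 2, colSums(adj), "/")
  n <- nrow(adj)
  e <- numeric(n)
  e[seed_idx] <- 1 / length(seed_idx)
  as.numeric(solve(diag(n) - (1 - r) * W, r * e))
}

# Grid-search maximizer of the Bernoulli log-likelihood over (beta0, beta1).
logistic_grid_oracle <- function(x, y, b0_range, b1_range, steps = 201) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  b0s <- seq(b0_range[1], b0_range[2], length.out = steps)
  b1s <- seq(b1_range[1], b1_range[2], length.out = steps)
  vals <- outer(b0s, b1s, Vectorize(ll))
  best <- arrayInd(which.max(vals), dim(vals))
  c(beta0 = b0s[best[1]], beta1 = b1s[best[2]])
}

# Direct BH step-up: q_i = min over tail of p_(j) * m / j, at the original order.
bh_direct_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# A small connected weighted graph as an edge tibble, for propagation tests.
random_edge_list <- function(n, p_edge = 0.15, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("N%03d", seq_len(n))
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p_edge
    # guarantee connectivity with a random spanning path
    ord <- sample(n)
    path <- cbind(ord[-n], ord[-1])
    idx <- rbind(t(pairs[, keep, drop = FALSE]), path)
    idx <- unique(cbind(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2])))
    tibble::tibble(gene_a = genes[pmin(idx[, 1], idx[, 2])],
                   gene_b = genes[pmax(idx[, 1], idx[, 2])],
                   weight = stats::runif(nrow(idx), 0.1, 1))
  })
}

# Tiny deterministic count_matrix for normalization tests.
toy_counts <- function(counts, n_subjects = ncol(counts) / 2) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("m%04d", seq_len(nrow(counts)))
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = 2),
    timepoint = rep(c("pre", "post"), n_subjects))
  evnetprop::count_matrix(counts, samples)
}
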