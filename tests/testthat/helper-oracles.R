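# Independent oracles and small fixture builders used across the suite.

# Exhaustive sliding-window scan: sort by value (stable), count anchors in
# every full window by explicit loop. Deliberately naive.
fir_oracle <- function(values, is_anchor, W) {
  ord <- order(values, seq_along(values))
  a <- is_anchor[ord]
  S <- length(values)
  best_k <- -1L
  best_start <- NA_integer_
  for (start in seq_len(S - W + 1L)) {
    k <- sum(a[start:(start + W - 1L)])
    if (k > best_k) {
      best_k <- k
      best_start <- start
    }
  }
  list(score = best_k / W, k_best = as.integer(best_k),
       window_start = best_start)
}

# Direct probability-mass summation of the upper binomial tail.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0L) return(1.0)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# Direct summation of the upper hypergeometric tail:
# P(X >= k) drawing n from a universe of N with K marked.
hyper_tail_oracle <- function(k, N, K, n) {
  lo <- max(k, 0L); hi <- min(n, K)
  if (lo > hi) return(0.0)
  sum(choose(K, lo:hi) * choose(N - K, n - (lo:hi))) / choose(N, n)
}

# Random named expression matrix.
rand_matrix <- function(n_genes, n_samples, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# Minimal phenotype table with the first `n_anchor` samples as anchors.
make_pheno <- function(sample_ids, n_anchor, group = NULL) {
  data.frame(sample_id = sample_ids,
             is_anchor = seq_along(sample_ids) <= n_anchor,
             group = group %||% ifelse(seq_along(sample_ids) <= n_anchor,
                                       "anchor", "other"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Planted-template matrix for module-recovery tests: `k` orthogonal block
# templates over the samples, `genes_per` genes per template, plus noise.
planted_modules <- function(k, genes_per, n_samples = 8L * k, sigma = 0.01,
                            seed = 1L) {
  set.seed(seed)
  block <- n_samples %/% k
  tpl <- matrix(0, k, n_samples)
  for (i in seq_len(k)) tpl[i, ((i - 1L) * block + 1L):(i * block)] <- 1
  x <- tpl[rep(seq_len(k), each = genes_per), , drop = FALSE] +
    matrix(rnorm(k * genes_per * n_samples, 0, sigma), k * genes_per)
  dimnames(x) <- list(sprintf("m%03d", seq_len(nrow(x))),
                      sprintf("s%03d", seq_len(n_samples)))
  list(matrix = x, truth = rep(seq_len(k), each = genes_per))
}

# Adjusted Rand index between two labelings (mclust as independent
# cross-check).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
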