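test_that("fir_score localizes anchors and matches hand-checked windows", {
  # two anchors carry the two smallest values: one window holds both
  v <- c(0.01, 0.02, 0.5, 0.6, 0.7, 0.8)
  a <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  f <- fir_score(v, a, W = 2L)
  expect_equal(f$score, 1.0)
  expect_equal(f$k_best, 2L)
  expect_equal(f$window_start, 1L)
  # anchors at sorted positions 2, 3, 5 with W = 3: best window holds 2
  v10 <- seq(0.1, 1.0, by = 0.1)
  a10 <- seq_along(v10) %in% c(2L, 3L, 5L)
  f10 <- fir_score(v10, a10, W = 3L)
  o10 <- fir_oracle(v10, a10, W = 3L)
  expect_equal(f10[c("score", "k_best", "window_start")],
               o10[c("score", "k_best", "window_start")])
  expect_equal(f10$score, 2 / 3)
  expect_equal(f10$window_start, 1L)
  # all samples anchors: perfect score at any width
  expect_equal(fir_score(v, rep(TRUE, 6L), W = 4L)$score, 1.0)
  expect_error(fir_score(v, a, W = 7L), "exceeds")
  expect_error(fir_score(v, rep(FALSE, 6L), W = 2L), "anchor")
})

test_that("fir_score equals the exhaustive window oracle on random genes", {
  set.seed(42)
  S <- 60L
  anchors <- seq_len(S) %in% sample(S, 12L)
  for (g in seq_len(200L)) {
    v <- rnorm(S)
    if (g %% 5L == 0L) v <- round(v, 1L)   # inject ties
    f <- fir_score(v, anchors, W = 12L)
    o <- fir_oracle(v, anchors, W = 12L)
    expect_identical(f$k_best, o$k_best)
    expect_equal(f$score, o$score)
    expect_identical(f$window_start, o$window_start)
  }
})

test_that("fir_score is invariant to strictly monotone transforms", {
  set.seed(5)
  v <- rnorm(30L)
  a <- seq_len(30L) %in% sample(30L, 6L)
  f0 <- fir_score(v, a, W = 6L)
  for (tr in list(function(z) exp(z), function(z) 3 * z - 7,
                  function(z) atan(z))) {
    expect_equal(fir_score(tr(v), a, W = 6L), f0)
  }
})

test_that("binomial_tail matches direct PMF summation and boundary cases", {
  expect_equal(binomial_tail(3L, 3L, 0.5), 0.125)
  expect_equal(binomial_tail(0L, 17L, 0.3), 1.0)
  expect_equal(binomial_tail(2L, 3L, 0.5), 0.5)
  for (n in c(1L, 5L, 20L, 60L)) for (p in c(0.05, 0.2, 0.5)) {
    for (k in 0L:n) {
      expect_equal(binomial_tail(k, n, p), binom_tail_oracle(k, n, p),
                   tolerance = 1e-12)
    }
  }
  expect_error(binomial_tail(5L, 3L, 0.5), "k")
  expect_error(binomial_tail(1L, 3L, 1.5), "p")
})

test_that("rank_genes ranks a perfectly localized gene first and matches the oracle", {
  set.seed(21)
  S <- 40L
  x <- rand_matrix(100L, S, seed = 21L)
  pheno <- make_pheno(colnames(x), n_anchor = 8L)
  # plant a gene whose anchor band no non-anchor value enters
  x["g001", ] <- c(runif(8L, 0.45, 0.55), runif(S - 8L, 0.6, 1.4))
  tab <- rank_genes(x, pheno)
  expect_equal(tab$gene_id[1L], "g001")
  expect_equal(tab$score[1L], 1.0)
  expect_equal(tab$rank[1L], 1L)
  # full-table agreement with the exhaustive oracle
  for (g in rownames(x)) {
    o <- fir_oracle(x[g, ], pheno$is_anchor, W = 8L)
    row <- tab[tab$gene_id == g, ]
    expect_equal(row$score, o$score)
    expect_equal(row$k_best, o$k_best)
    expect_equal(row$p_value, binom_tail_oracle(o$k_best, 8L, 8L / S),
                 tolerance = 1e-12)
  }
  # permuting gene rows leaves the sorted table unchanged
  perm <- sample(nrow(x))
  tab2 <- rank_genes(x[perm, ], pheno)
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # dense ranks: consecutive integers starting at 1
  expect_equal(sort(unique(tab$rank)), seq_len(max(tab$rank)))
})

test_that("adding a non-anchor sample outside every best window never lowers scores", {
  set.seed(9)
  x <- rand_matrix(50L, 30L, seed = 9L)
  pheno <- make_pheno(colnames(x), n_anchor = 6L)
  tab <- rank_genes(x, pheno)
  # append one non-anchor sample with values above every gene's range
  x2 <- cbind(x, s_new = apply(x, 1L, max) + 1)
  pheno2 <- rbind(pheno, data.frame(sample_id = "s_new", is_anchor = FALSE,
                                    group = "other"))
  tab2 <- rank_genes(x2, pheno2, W = 6L)
  m <- match(tab$gene_id, tab2$gene_id)
  expect_true(all(tab2$score[m] >= tab$score))
})

test_that("t_percentile ranks mean-shift genes, not range-specific ones", {
  set.seed(31)
  S <- 60L
  x <- rand_matrix(200L, S, seed = 31L)
  pheno <- make_pheno(colnames(x), n_anchor = 10L)
  # strong mean-shift gene vs a no-shift gene
  x["g001", ] <- c(rnorm(10L, 5), rnorm(50L, 0))
  x["g002", ] <- rnorm(S)
  expect_gt(t_percentile(x, pheno, "g001"), t_percentile(x, pheno, "g002"))
  # identical values give identical percentiles
  x["g003", ] <- x["g001", ]
  expect_equal(t_percentile(x, pheno, "g003"), t_percentile(x, pheno, "g001"))
  expect_error(t_percentile(x, make_pheno(colnames(x), 1L), "g001"), ">= 2")
})

test_that("symmetric-bimodal genes rank high by window score, low by t", {
  # the discordance a mean-shift test misses: anchors in a tight band,
  # non-anchors straddling it symmetrically
  wins <- 0L
  for (seed in 1:20) {
    sim <- simulate_landscape(landscape_config(
      n_genes = 300L, n_samples = 100L,
      group_sizes = c(pluripotent = 10L, normal = 90L),
      group_stemness = c(pluripotent = 1, normal = 0.1),
      n_planted_gradient = 0L, n_planted_band = 5L,
      bimodal_fraction = 1, seed = seed))
    x <- rank_normalize(sim$matrix)
    tab <- rank_genes(x, sim$pheno)
    G <- nrow(tab)
    for (g in sim$truth$bimodal_genes) {
      fir_pct <- 100 * (G - which(tab$gene_id == g) + 1L) / G
      t_pct <- t_percentile(x, sim$pheno, g)
      if (fir_pct > t_pct) wins <- wins + 1L
      expect_gt(fir_pct, 90)   # window score puts it in the top decile
    }
  }
  expect_gte(wins / 100, 0.95)
})

test_that("select_signature returns rank prefixes or score cuts", {
  tab <- structure(data.frame(gene_id = c("a", "b", "c", "d", "e"),
                              score = c(1, 1, 0.8, 0.6, 0.4),
                              k_best = c(5L, 5L, 4L, 3L, 2L),
                              window_start = 1L,
                              p_value = c(.01, .02, .1, .3, .6),
                              rank = c(1L, 1L, 2L, 3L, 4L)),
                   class = c("gene_score_table", "data.frame"), W = 5L)
  expect_identical(unclass(select_signature(tab, top_n = 3L))[1:3],
                   c("a", "b", "c"))
  expect_identical(unclass(select_signature(tab, min_score = 1.0))[1:2],
                   c("a", "b"))
  expect_length(select_signature(tab, top_n = 5L), 5L)
  expect_error(select_signature(tab, top_n = 6L), "between")
  expect_error(select_signature(tab), "exactly one")
})

test_that("one_way_f reproduces hand-computed sums of squares", {
  f <- one_way_f(c(1, 2, 4, 5), c("A", "A", "B", "B"))
  expect_equal(f$F, 18)                      # SSB = 9, SSW = 1, df (1, 2)
  expect_equal(f$df_between, 1L)
  expect_equal(f$df_within, 2L)
  # equal group means with within-variance: F = 0
  expect_equal(one_way_f(c(1, 3, 1, 3), c("A", "A", "B", "B"))$F, 0)
  # zero total variance: defined as 0
  expect_equal(one_way_f(rep(2, 6), rep(c("A", "B"), 3L))$F, 0)
  # permutation within groups leaves F unchanged
  set.seed(2)
  v <- rnorm(12L); g <- rep(c("A", "B", "C"), each = 4L)
  perm <- ave(seq_along(v), g, FUN = sample)
  expect_equal(one_way_f(v[perm], g[perm])$F, one_way_f(v, g)$F)
  expect_error(one_way_f(1:3, rep("A", 3L)), "2 groups")
})

test_that("threshold sweep scores separation across the size grid", {
  sim <- simulate_landscape(landscape_config(
    n_genes = 400L, n_samples = 200L,
    group_sizes = c(pluripotent = 20L, multipotent = 40L, cancer = 70L,
                    normal = 70L),
    group_stemness = c(pluripotent = 1, multipotent = 0.7, cancer = 0.4,
                       normal = 0.1),
    n_planted_gradient = 50L, n_planted_band = 0L, seed = 4L))
  x <- rank_normalize(sim$matrix)
  groups <- unique(sim$pheno$group)
  sw <- threshold_sweep(x, sim$pheno, n_grid = c(3L, 10L, 50L, 200L),
                        eval_groups = groups)
  best <- attr(sw, "best_n")
  expect_true(best %in% sw$n_genes)
  expect_gte(sw$F[sw$n_genes == best], sw$F[sw$n_genes == 3L])
  expect_gte(sw$F[sw$n_genes == best], sw$F[sw$n_genes == 200L])
  # single-size grid degenerates to that size
  sw1 <- threshold_sweep(x, sim$pheno, n_grid = 25L, eval_groups = groups)
  expect_equal(nrow(sw1), 1L)
  expect_equal(attr(sw1, "best_n"), 25L)
  expect_error(threshold_sweep(x, sim$pheno, n_grid = 10L,
                               eval_groups = "nope"), "absent")
})
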