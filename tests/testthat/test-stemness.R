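test_that("a single-gene signature returns the centered gene as the index", {
  x <- matrix(c(1, 2, 3), 1L, dimnames = list("g1", c("s1", "s2", "s3")))
  pheno <- data.frame(sample_id = c("s1", "s2", "s3"),
                      is_anchor = c(FALSE, FALSE, TRUE),
                      group = c("a", "a", "top"), stringsAsFactors = FALSE)
  st <- compute_stemness(x, "g1", orientation_group = "top", pheno = pheno)
  expect_equal(unname(st$index), c(-1, 0, 1))
  expect_equal(mean(st$index), 0)
  expect_equal(sum(st$loadings^2), 1)
})

test_that("perfectly collinear genes give closed-form loadings and full PC1 variance", {
  g1 <- c(0.2, 0.5, 0.9, 0.1, 0.7)
  x <- rbind(g1 = g1, g2 = 2 * g1)
  colnames(x) <- sprintf("s%d", 1:5)
  st <- compute_stemness(x, c("g1", "g2"))
  expect_equal(st$variance_explained[1L], 1.0)
  expect_equal(abs(unname(st$loadings)), c(1, 2) / sqrt(5))
  # fallback orientation: the largest-|loading| gene has a positive loading
  expect_gt(st$loadings[["g2"]], 0)
})

test_that("the index is orientation-, shift- and scale-consistent", {
  x <- rand_matrix(20L, 15L, seed = 13L)
  pheno <- make_pheno(colnames(x), 4L, group = rep(c("stem", "rest"),
                                                   c(4L, 11L)))
  sig <- rownames(x)[1:10]
  st <- compute_stemness(x, sig, orientation_group = "stem", pheno = pheno)
  expect_gte(mean(st$index[pheno$sample_id[pheno$group == "stem"]]), 0)
  # adding per-gene constants changes nothing (centering)
  x2 <- x + matrix(rnorm(nrow(x)), nrow(x), ncol(x))
  st2 <- compute_stemness(x2, sig, orientation_group = "stem", pheno = pheno)
  expect_equal(st2$index, st$index)
  # global positive scaling scales the index, preserving order
  st3 <- compute_stemness(3 * x, sig, orientation_group = "stem",
                          pheno = pheno)
  expect_equal(st3$index, 3 * st$index)
  # variance fractions: non-increasing, summing to 1
  expect_true(all(diff(st$variance_explained) <= 1e-12))
  expect_equal(sum(st$variance_explained), 1)
})

test_that("coverage below one half errors with the missing genes listed", {
  x <- rand_matrix(10L, 8L, seed = 1L)
  sig <- c(rownames(x)[1:3], sprintf("zz%02d", 1:4))
  expect_error(compute_stemness(x, sig), "coverage.*zz01")
  # coverage exactly 0.5 succeeds
  sig2 <- c(rownames(x)[1:3], sprintf("zz%02d", 1:3))
  st <- compute_stemness(x, sig2)
  expect_length(st$genes_missing, 3L)
  expect_error(compute_stemness(x[, 1:2], rownames(x)[1:3]), ">= 3 samples")
  xc <- matrix(1, 3L, 4L, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_error(compute_stemness(xc, letters[1:3]), "covariance")
})

test_that("predict projects new samples onto the frozen basis", {
  x <- rand_matrix(12L, 10L, seed = 8L)
  st <- compute_stemness(x, rownames(x)[1:6])
  expect_equal(predict(st, x), st$index)
  expect_equal(unname(predict(st, x[, 3L, drop = FALSE])),
               unname(st$index[3L]))
  expect_error(predict(st, x[7:12, , drop = FALSE]), "lacks")
  expect_equal(unname(coef(st)), unname(st$loadings))
})

test_that("per-series fits are independent and fail per series", {
  x1 <- rand_matrix(15L, 9L, seed = 2L)
  x2 <- x1 * 10      # scaled copy: same ordering, scaled index
  x3 <- x1[1:5, ]    # only 1/3 of the signature present
  sig <- rownames(x1)
  res <- stemness_per_series(list(a = x1, b = x2, c = x3), sig)
  expect_s3_class(res$a, "stemness")
  expect_equal(res$b$index, 10 * res$a$index)
  expect_identical(order(res$b$index), order(res$a$index))
  expect_s3_class(res$c, "try-error")
  # duplicate series give identical indices
  res2 <- stemness_per_series(list(a = x1, a2 = x1), sig)
  expect_equal(res2$a2$index, res2$a$index)
})

test_that("ordered separation summarizes monotone indices and is sign-free", {
  idx <- 1:12
  lab <- factor(rep(c("d0", "d4", "d8", "d14"), each = 3L),
                levels = c("d0", "d4", "d8", "d14"), ordered = TRUE)
  sep <- ordered_separation(idx, lab)
  # tied level codes attenuate Spearman below 1 even for perfect monotone
  # separation; the maximum attainable here is cor(rank(idx), tied codes)
  expect_equal(sep$spearman_rho_abs,
               cor(rank(idx), rank(as.integer(lab))))
  expect_gt(sep$spearman_rho_abs, 0.95)
  expect_true(all(sep$auc[upper.tri(sep$auc)] == 1.0))
  sep_neg <- ordered_separation(-idx, lab)
  expect_equal(sep_neg$spearman_rho_abs, sep$spearman_rho_abs)
  expect_equal(sep_neg$auc, sep$auc)
  expect_error(ordered_separation(idx, rep("one", 12L)), "2 ordered levels")
})

test_that("ordered separation is near zero under label shuffling", {
  set.seed(77)
  rhos <- replicate(30L, {
    idx <- rnorm(200L)
    lab <- factor(sample(rep(c("a", "b", "c", "d"), each = 50L)),
                  levels = c("a", "b", "c", "d"), ordered = TRUE)
    ordered_separation(idx, lab)$spearman_rho_abs
  })
  expect_lt(mean(rhos), 0.1)   # |rho| of a null has small positive mean
  expect_lt(max(rhos), 0.3)
})

test_that("cross-species transfer maps, filters and preserves the index", {
  x <- rand_matrix(20L, 12L, seed = 6L)
  sig <- rownames(x)[1:8]
  ident <- setNames(rownames(x), rownames(x))
  st0 <- compute_stemness(x, sig)
  st1 <- cross_species_index(x, sig, ident)
  expect_equal(st1$index, st0$index)
  # mouse-style ids: map half the signature (coverage exactly 0.5)
  xm <- x
  rownames(xm) <- paste0("m_", rownames(x))
  half <- setNames(paste0("m_", sig[1:4]), sig[1:4])
  st2 <- cross_species_index(xm, sig, half)
  expect_length(st2$genes_used, 4L)
  expect_identical(attr(st2, "unmapped"), sig[5:8])
  # a shared target excludes the colliding pair
  m3 <- c(setNames(paste0("m_", sig[1:6]), sig[1:6]),
          setNames("m_shared", sig[7L]), setNames("m_shared", sig[8L]))
  st3 <- cross_species_index(xm, sig, m3)
  expect_length(st3$genes_used, 6L)
  # below-coverage map errors with counts
  expect_error(cross_species_index(xm, sig, half[1:3]), "coverage")
})
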