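# Sliding-window (finite-impulse-response) specificity scoring.
#
# For one gene, samples are sorted by expression value and a window of fixed
# width W slides over the sorted list; the score is the maximum fraction of
# anchor samples found in any window. Unlike a t-test, the statistic rewards
# a tight anchor band anywhere along the intensity spectrum, even when
# non-anchor samples straddle the band from both sides.

#' Sliding-window specificity score for one gene
#'
#' Samples are sorted ascending by value (ties broken stably by original
#' position); over all `S - W + 1` full contiguous windows of width `W`,
#' returns the maximum anchor fraction, the anchor count in that window,
#' and the earliest window start attaining it.
#'
#' @param values Numeric vector of per-sample expression values.
#' @param is_anchor Logical vector, same length, at least one `TRUE`.
#' @param W Window width, `1 <= W <= length(values)`. Conventionally the
#'   total number of anchor samples, so a score of 1 means every anchor
#'   fits in one window.
#' @return List with `score` (`k_best / W`), `k_best`, `window_start`
#'   (1-based index into the sorted order).
#' @export
fir_score <- function(values, is_anchor, W) {
  S <- length(values)
  if (length(is_anchor) != S) stop("values and is_anchor lengths differ")
  W <- as.integer(W)
  if (is.na(W) || W < 1L) stop("W must be a positive integer")
  if (W > S) stop("window width W (", W, ") exceeds sample count (", S, ")")
  if (!any(is_anchor)) stop("no anchor samples")
  ord <- order(values, seq_along(values))     # stable tie-break by position
  cs <- c(0L, cumsum(as.integer(is_anchor[ord])))
  counts <- cs[(W + 1L):(S + 1L)] - cs[1L:(S - W + 1L)]
  k_best <- max(counts)
  list(score = k_best / W,
       k_best = as.integer(k_best),
       window_start = which.max(counts))      # earliest maximal window
}

#' Upper binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`; the reported p-value for a window
#' holding `k` anchors out of `n = W` slots when anchors make up a fraction
#' `p` of all samples.
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials.
#' @param p Success probability.
#' @return Tail probability in (0, 1].
#' @export
binomial_tail <- function(k, n, p) {
  if (any(k < 0L | k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  stats::pbinom(k - 1L, size = n, prob = p, lower.tail = FALSE)
}

#' Score and rank every gene by anchor specificity
#'
#' Applies [fir_score()] to each gene row and attaches the binomial tail
#' p-value (`n = W`, `p` = anchor fraction of all samples). Rows are sorted
#' by descending score, ties by ascending p-value then gene id, and dense
#' ranks (by score) assigned.
#'
#' @param x Expression matrix, features x samples.
#' @param pheno Phenotype table with `sample_id` and `is_anchor`; every
#'   phenotype sample must be a matrix column (extra matrix columns are
#'   ignored).
#' @param W Window width; `"auto"` (default) uses the anchor count.
#' @return A `gene_score_table`: data.frame with columns `gene_id`,
#'   `score`, `k_best`, `window_start`, `p_value`, `rank`.
#' @export
rank_genes <- function(x, pheno, W = "auto") {
  validate_expression_matrix(x)
  x <- align_phenotypes(x, pheno)
  anchors <- pheno$is_anchor
  if (!any(anchors) || all(anchors))
    stop("need at least one anchor and one non-anchor sample")
  if (identical(W, "auto")) W <- sum(anchors)
  W <- as.integer(W)
  S <- ncol(x)
  p_bg <- sum(anchors) / S
  res <- vapply(seq_len(nrow(x)), function(i) {
    f <- fir_score(x[i, ], anchors, W)
    c(f$score, f$k_best, f$window_start)
  }, numeric(3L))
  tab <- data.frame(gene_id = rownames(x),
                    score = res[1L, ],
                    k_best = as.integer(res[2L, ]),
                    window_start = as.integer(res[3L, ]),
                    p_value = binomial_tail(as.integer(res[2L, ]), W, p_bg),
                    stringsAsFactors = FALSE)
  ord <- order(-tab$score, tab$p_value, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- match(-tab$score, sort(unique(-tab$score)))  # dense rank by score
  rownames(tab) <- NULL
  structure(tab, class = c("gene_score_table", "data.frame"),
            W = W, anchor_fraction = p_bg, n_samples = S)
}

#' @export
print.gene_score_table <- function(x, n = 10L, ...) {
  cat("Anchor-specificity gene ranking: ", nrow(x), " genes, window W = ",
      attr(x, "W"), ", anchor fraction = ",
      signif(attr(x, "anchor_fraction"), 3L), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), ...)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more genes\n", sep = "")
  invisible(x)
}

#' Percentile of a gene under a two-sample t contrast
#'
#' Computes for every gene the pooled-variance two-sample t statistic
#' (anchors vs all non-anchors, or Welch if requested) and returns the
#' named gene's percentile among all genes by absolute t (100 =
#' strongest). The contrast a mean-shift test performs; genes whose
#' non-anchor values straddle the anchor band symmetrically score low here
#' while ranking high by [fir_score()].
#'
#' @param x Expression matrix.
#' @param pheno Phenotype table (>= 2 anchors and >= 2 non-anchors).
#' @param gene_id Gene to report.
#' @param welch Use Welch (unequal-variance) t instead of pooled.
#' @return Percentile in (0, 100].
#' @export
t_percentile <- function(x, pheno, gene_id, welch = FALSE) {
  stat <- t_statistics(x, pheno, welch = welch)
  if (!gene_id %in% names(stat)) stop("unknown gene id: ", gene_id)
  unname(100 * rank(abs(stat), ties.method = "average")[gene_id] / length(stat))
}

# Vectorized two-sample t statistics per gene row.
t_statistics <- function(x, pheno, welch = FALSE) {
  validate_expression_matrix(x)
  x <- align_phenotypes(x, pheno)
  a <- pheno$is_anchor
  n1 <- sum(a); n2 <- sum(!a)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 anchor and >= 2 non-anchor samples")
  x1 <- x[, a, drop = FALSE]; x2 <- x[, !a, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
  }
  d <- m1 - m2
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf * sign(d)))
  stats::setNames(t, rownames(x))
}

#' Select a signature from a ranked gene table
#'
#' @param table A `gene_score_table` from [rank_genes()].
#' @param top_n Keep the `top_n` best-ranked genes (a prefix of the table).
#' @param min_score Alternatively, keep all genes with `score >= min_score`.
#' @return Character vector of gene ids in rank order, class
#'   `signature_genes`, carrying the selection rule and window as
#'   attributes.
#' @export
select_signature <- function(table, top_n = NULL, min_score = NULL) {
  if (is.null(top_n) == is.null(min_score))
    stop("give exactly one of top_n or min_score")
  if (!is.null(top_n)) {
    top_n <- as.integer(top_n)
    if (top_n < 1L || top_n > nrow(table))
      stop("top_n must be between 1 and the gene count (", nrow(table), ")")
    ids <- table$gene_id[seq_len(top_n)]
    rule <- list(top_n = top_n)
  } else {
    ids <- table$gene_id[table$score >= min_score]
    rule <- list(min_score = min_score)
  }
  structure(ids, class = "signature_genes", rule = rule, W = attr(table, "W"))
}

#' @export
print.signature_genes <- function(x, ...) {
  rule <- attr(x, "rule")
  cat("Signature of ", length(x), " genes (",
      paste(names(rule), unlist(rule), sep = " = "), ")\n", sep = "")
  cat(paste(utils::head(unclass(x), 8L), collapse = ", "),
      if (length(x) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' One-way fixed-effects analysis of variance
#'
#' Classic one-way F on a numeric response across groups. A response with
#' zero total variance returns F = 0 (rather than an error) so parameter
#' sweeps over degenerate inputs complete.
#'
#' @param values Numeric vector.
#' @param groups Categorical vector, >= 2 non-empty groups.
#' @return List with `F`, `df_between`, `df_within`.
#' @export
one_way_f <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  if (df_w < 1L) stop("no within-group degrees of freedom")
  if (sum((values - mean(values))^2) == 0)
    return(list(F = 0, df_between = df_b, df_within = df_w))
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic),
       df_between = as.integer(unname(ft$parameter[1L])),
       df_within = as.integer(unname(ft$parameter[2L])))
}

#' Sweep the signature size and score multi-group separation
#'
#' For each candidate size `n` in `n_grid`: select the top-`n` signature,
#' compute the stemness index over the full matrix, and measure the
#' one-way F of the index across `eval_groups`. Larger F means better
#' simultaneous separation of the evaluated phenotypes along the index.
#'
#' @param x Expression matrix.
#' @param pheno Phenotype table.
#' @param n_grid Integer vector of candidate signature sizes.
#' @param eval_groups Group labels (from `pheno$group`) entering the F
#'   statistic.
#' @param W Window width passed to [rank_genes()].
#' @param orientation_group Group used to orient the index sign (defaults
#'   to the first eval group).
#' @param table Optional precomputed `gene_score_table` (avoids rescoring).
#' @return Data.frame `n_genes`, `F`, class `threshold_sweep`, with the
#'   argmax size in attribute `best_n`.
#' @export
threshold_sweep <- function(x, pheno, n_grid, eval_groups, W = "auto",
                            orientation_group = eval_groups[1L],
                            table = NULL) {
  n_grid <- as.integer(n_grid)
  if (is.null(table)) table <- rank_genes(x, pheno, W = W)
  if (any(n_grid < 1L) || any(n_grid > nrow(table)))
    stop("n_grid values must lie in [1, ", nrow(table), "]")
  miss <- setdiff(eval_groups, unique(pheno$group))
  if (length(miss)) stop("eval group(s) absent: ", paste(miss, collapse = ", "))
  keep <- pheno$group %in% eval_groups
  fs <- vapply(n_grid, function(n) {
    sig <- select_signature(table, top_n = n)
    st <- compute_stemness(x, sig, orientation_group = orientation_group,
                           pheno = pheno)
    one_way_f(st$index[pheno$sample_id[keep]], pheno$group[keep])$F
  }, numeric(1L))
  out <- data.frame(n_genes = n_grid, F = fs)
  structure(out, class = c("threshold_sweep", "data.frame"),
            best_n = n_grid[which.max(fs)])
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Signature-size sweep over", nrow(x), "sizes; best separation at n =",
      attr(x, "best_n"), "\n")
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' @export
plot.threshold_sweep <- function(x, ...) {
  plot(x$n_genes, x$F, type = "b", xlab = "signature size (genes)",
       ylab = "one-way F of stemness index", ...)
  graphics::abline(v = attr(x, "best_n"), lty = 2L)
  invisible(x)
}
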