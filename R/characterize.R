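# Post-hoc signature characterization: correlation null against random gene
# sets, coexpression module clustering, hypergeometric over-representation.

#' Compare signature gene-gene correlations to random gene sets
#'
#' Within each sample group, computes the Pearson correlation of every
#' signature gene pair, then draws `n_random` random gene sets of the same
#' size from the full gene universe and pools their pairwise correlations
#' into a null distribution. The location shift (observed median minus
#' null median) diagnoses whether the signature is merely a globally
#' coexpressed module: a specificity-driven signature should show little
#' or no shift in most sample groups.
#'
#' @param x Expression matrix.
#' @param sig Signature gene ids (>= 2, fewer than the universe).
#' @param groups Named list mapping group name -> character vector of
#'   sample ids; each group needs >= 3 samples.
#' @param n_random Number of random sets (default 1000).
#' @param seed Integer seed for the random draws.
#' @param exclude_signature Draw random sets from the universe minus the
#'   signature (default `FALSE`: the full universe, signature included).
#' @return `correlation_null` object: per group, the observed correlation
#'   vector, pooled null vector, per-set null medians, `location_shift`,
#'   and the count of pairs excluded for zero variance.
#' @export
correlation_null <- function(x, sig, groups, n_random = 1000L, seed = 1L,
                             exclude_signature = FALSE) {
  validate_expression_matrix(x)
  sig <- unique(as.character(sig))
  m <- length(sig)
  if (m < 2L) stop("signature must contain >= 2 genes")
  if (!all(sig %in% rownames(x)))
    stop("signature gene(s) absent from matrix: ",
         paste(utils::head(setdiff(sig, rownames(x)), 5L), collapse = ", "))
  universe <- rownames(x)
  if (exclude_signature) universe <- setdiff(universe, sig)
  if (length(universe) <= m) stop("gene universe must exceed signature size")
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a named list of sample-id vectors")
  rs <- .seeded_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  draws <- lapply(seq_len(n_random),
                  function(i) sample(universe, m, replace = FALSE))
  per_group <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) < 3L) stop("group '", g, "' has < 3 samples")
    bad <- setdiff(ids, colnames(x))
    if (length(bad)) stop("group '", g, "' names unknown sample(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    obs <- pair_correlations(x[sig, ids, drop = FALSE])
    null_sets <- lapply(draws, function(gs)
      pair_correlations(x[gs, ids, drop = FALSE]))
    pooled <- unlist(null_sets, use.names = FALSE)
    excluded <- (m * (m - 1L) / 2) - length(obs$r)
    if (obs$n_excluded)
      message("group '", g, "': excluded ", obs$n_excluded,
              " pair(s) with a zero-variance gene")
    list(observed = obs$r,
         null = pooled,
         null_set_medians = vapply(null_sets,
                                   function(z) stats::median(z$r), numeric(1L)),
         location_shift = stats::median(obs$r) - stats::median(pooled),
         n_excluded = obs$n_excluded)
  })
  names(per_group) <- names(groups)
  structure(list(groups = per_group, m = m, n_random = n_random, seed = seed),
            class = "correlation_null")
}

# Upper-triangle Pearson correlations of the rows of `sub`; pairs involving
# a constant row are excluded (they have no defined correlation).
pair_correlations <- function(sub) {
  keep <- apply(sub, 1L, stats::sd) > 0
  n_excl_rows <- sum(!keep)
  m <- nrow(sub)
  r_full_pairs <- m * (m - 1L) / 2
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < 2L)
    return(list(r = numeric(0L), n_excluded = r_full_pairs))
  cm <- stats::cor(t(sub))
  r <- cm[upper.tri(cm)]
  list(r = r, n_excluded = r_full_pairs - length(r))
}

#' @export
print.correlation_null <- function(x, ...) {
  cat("Signature correlation null: m = ", x$m, " genes, ", x$n_random,
      " random sets (seed ", x$seed, ")\n", sep = "")
  for (g in names(x$groups)) {
    z <- x$groups[[g]]
    band <- stats::quantile(z$null_set_medians - stats::median(z$null),
                            c(0.025, 0.975), names = FALSE)
    cat(sprintf("  %-14s location shift %+.4f (null-set median band [%+.4f, %+.4f])\n",
                g, z$location_shift, band[1L], band[2L]))
  }
  invisible(x)
}

#' Cluster signature genes into coexpression modules
#'
#' Agglomerative hierarchical clustering of per-gene-normalized signature
#' rows (Euclidean distance), cut into `k` modules. Module labels are
#' renumbered by dendrogram left-to-right order so the assignment is
#' deterministic and invariant to the input row order.
#'
#' @param x Expression matrix.
#' @param sig Signature gene ids, all present in `x`.
#' @param k Number of modules (default 4).
#' @param normalization Per-gene `"zscore"` (default) or `"quantile"`
#'   (fractional ranks within each gene row).
#' @param linkage `"complete"` (default) or `"average"`.
#' @param drop_zero_var Drop zero-variance genes under zscore instead of
#'   erroring.
#' @return Named integer vector gene -> module in 1..k, class
#'   `cluster_assignment`, with the `hclust` tree in attribute `tree`.
#' @export
cluster_signature <- function(x, sig, k = 4L,
                              normalization = c("zscore", "quantile"),
                              linkage = c("complete", "average"),
                              drop_zero_var = FALSE) {
  normalization <- match.arg(normalization)
  linkage <- match.arg(linkage)
  validate_expression_matrix(x)
  sig <- unique(as.character(sig))
  miss <- setdiff(sig, rownames(x))
  if (length(miss)) stop("signature gene(s) absent: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  sub <- x[sig, , drop = FALSE]
  if (normalization == "zscore") {
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0)) {
      if (drop_zero_var) {
        sub <- sub[sds > 0, , drop = FALSE]
      } else {
        stop("zero-variance gene(s) under zscore normalization: ",
             paste(utils::head(rownames(sub)[sds == 0], 5L), collapse = ", "))
      }
    }
    sub <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  } else {
    G <- ncol(sub)
    sub <- t(apply(sub, 1L, function(r) rank(r, ties.method = "average") / G))
  }
  k <- as.integer(k)
  if (k < 1L || k > nrow(sub)) stop("k must lie in [1, ", nrow(sub), "]")
  hc <- stats::hclust(stats::dist(sub), method = linkage)
  raw <- stats::cutree(hc, k = k)
  # renumber modules by first appearance along the dendrogram leaf order
  first_seen <- unique(raw[hc$order])
  modules <- match(raw, first_seen)
  names(modules) <- names(raw)
  structure(modules[sig[sig %in% names(modules)]],
            class = "cluster_assignment", k = k,
            normalization = normalization, linkage = linkage, tree = hc)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Coexpression modules: ", attr(x, "k"), " modules over ", length(x),
      " genes (", attr(x, "normalization"), " normalization, ",
      attr(x, "linkage"), " linkage)\n", sep = "")
  print(table(module = unclass(x)))
  invisible(x)
}

#' Hypergeometric over-representation of a gene module
#'
#' For each gene set in the collection (intersected with the universe),
#' tests whether the module's overlap with it is larger than expected by
#' chance: `p = P(X >= k)` under the hypergeometric null of drawing the
#' module uniformly from the universe.
#'
#' @param module_genes Gene ids of the module (must lie in `universe`).
#' @param universe All testable gene ids.
#' @param collection Named list of gene sets (see [read_gene_sets()]).
#' @param adjust Apply Benjamini-Hochberg correction (`p_adj` column).
#' @return Data.frame with `set`, `overlap`, `set_size`, `module_size`,
#'   `universe_size`, `p` (and `p_adj`), sorted ascending by `p`.
#' @export
hypergeom_enrichment <- function(module_genes, universe, collection,
                                 adjust = FALSE) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  module_genes <- unique(as.character(module_genes))
  out_mod <- setdiff(module_genes, universe)
  if (length(out_mod))
    stop("module gene(s) outside universe: ",
         paste(utils::head(out_mod, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(module_genes)
  rows <- lapply(names(collection), function(s) {
    set <- intersect(collection[[s]], universe)
    K <- length(set)
    k <- length(intersect(set, module_genes))
    p <- if (k == 0L) 1.0 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, overlap = k, set_size = K, module_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), overlap = integer(),
                      set_size = integer(), module_size = integer(),
                      universe_size = integer(), p = numeric())
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
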