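# The stemness index: PC1 of the gene-gene covariance over a signature.
#
# Signature gene rows are mean-centered (no variance scaling: inputs are
# already rank-bounded and the covariance, not correlation, matrix defines
# the summary). The leading eigenvector of the gene-gene covariance gives
# the loadings; each sample's projection onto it is its index. The sign is
# fixed by an orientation group (its mean index forced non-negative) or,
# failing that, by making the largest-|loading| gene's loading positive.

#' Fit the stemness index over a gene signature
#'
#' @param x Expression matrix, features x samples (>= 3 samples).
#' @param sig Character vector of signature gene ids (order irrelevant);
#'   at least half must be present in `x` (coverage rule), else an error
#'   listing the missing genes.
#' @param orientation_group Optional group label from `pheno$group`; the
#'   mean index of that group is forced >= 0. When absent or `NULL`, the
#'   fallback sign rule (largest-|loading| gene positive) applies.
#' @param pheno Optional phenotype table (required when
#'   `orientation_group` is given).
#' @return An object of class `stemness`: list with `loadings` (unit
#'   vector, named by gene), `index` (named per-sample scalar, mean 0),
#'   `variance_explained`, `center` (per-gene means), `genes_used`,
#'   `genes_missing`, `orientation_group`, `flipped`.
#' @export
compute_stemness <- function(x, sig, orientation_group = NULL, pheno = NULL) {
  validate_expression_matrix(x)
  sig <- unique(as.character(sig))
  genes_used <- intersect(sig, rownames(x))
  genes_missing <- setdiff(sig, rownames(x))
  if (length(sig) < 1L) stop("empty signature")
  coverage <- length(genes_used) / length(sig)
  if (coverage < 0.5)
    stop("signature coverage ", signif(coverage, 3L),
         " below 0.5; missing genes: ",
         paste(utils::head(genes_missing, 10L), collapse = ", "),
         if (length(genes_missing) > 10L) ", ..." else "")
  if (ncol(x) < 3L) stop("need >= 3 samples")
  sub <- x[genes_used, , drop = FALSE]
  ctr <- rowMeans(sub)
  subc <- sub - ctr
  cv <- tcrossprod(subc) / (ncol(subc) - 1L)   # gene-gene covariance
  if (all(cv == 0)) stop("zero covariance matrix: signature genes are constant")
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  loadings <- eg$vectors[, 1L]
  names(loadings) <- genes_used
  index <- as.vector(crossprod(subc, loadings))
  names(index) <- colnames(x)
  flipped <- FALSE
  og <- orientation_group
  if (!is.null(og) && !is.null(pheno) && og %in% pheno$group) {
    grp <- pheno$sample_id[pheno$group == og]
    grp <- intersect(grp, names(index))
    if (length(grp)) {
      if (mean(index[grp]) < 0) flipped <- TRUE
    } else og <- NULL
  } else og <- NULL
  if (is.null(og)) {
    # deterministic fallback: largest-|loading| gene gets a positive loading
    top <- which.max(abs(loadings))
    if (loadings[top] < 0) flipped <- TRUE
  }
  if (flipped) { loadings <- -loadings; index <- -index }
  structure(list(loadings = loadings,
                 index = index,
                 variance_explained = ev / sum(ev),
                 center = ctr,
                 genes_used = genes_used,
                 genes_missing = genes_missing,
                 orientation_group = og,
                 flipped = flipped),
            class = "stemness")
}

#' @export
print.stemness <- function(x, ...) {
  cat("Stemness index over ", length(x$genes_used), " signature genes, ",
      length(x$index), " samples\n", sep = "")
  cat("PC1 variance explained: ",
      sprintf("%.1f%%", 100 * x$variance_explained[1L]), "\n", sep = "")
  if (!is.null(x$orientation_group))
    cat("Oriented so group '", x$orientation_group, "' has mean index >= 0",
        if (x$flipped) " (sign flipped)", "\n", sep = "")
  cat("Index range: [", signif(min(x$index), 4L), ", ",
      signif(max(x$index), 4L), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.stemness <- function(object, ...) {
  cat("Stemness fit\n")
  cat("  genes used:    ", length(object$genes_used), "\n")
  cat("  genes missing: ", length(object$genes_missing), "\n")
  cat("  samples:       ", length(object$index), "\n")
  ve <- utils::head(object$variance_explained, 5L)
  cat("  variance explained (leading components):",
      paste(sprintf("%.3f", ve), collapse = " "), "\n")
  cat("  top |loading| genes:\n")
  top <- utils::head(order(-abs(object$loadings)), 5L)
  print(signif(object$loadings[top], 4L))
  invisible(object)
}

#' @export
coef.stemness <- function(object, ...) object$loadings

#' Project new samples onto frozen stemness loadings
#'
#' By default the index is refit per dataset; projection onto a previously
#' fitted basis is an explicitly separate mode for when two datasets must
#' share one coordinate system. Genes are centered with the training means.
#'
#' @param object A `stemness` fit.
#' @param newdata Expression matrix containing all `genes_used`.
#' @param ... Unused.
#' @return Named numeric vector of projected index values.
#' @export
predict.stemness <- function(object, newdata, ...) {
  validate_expression_matrix(newdata)
  miss <- setdiff(object$genes_used, rownames(newdata))
  if (length(miss))
    stop("newdata lacks fitted signature gene(s): ",
         paste(utils::head(miss, 10L), collapse = ", "))
  sub <- newdata[object$genes_used, , drop = FALSE] - object$center
  stats::setNames(as.vector(crossprod(sub, object$loadings)), colnames(newdata))
}

#' @export
plot.stemness <- function(x, groups = NULL, ...) {
  if (is.null(groups)) {
    plot(sort(x$index), seq_along(x$index), xlab = "stemness index",
         ylab = "sample (sorted)", ...)
  } else {
    groups <- factor(groups)
    graphics::stripchart(split(x$index, groups), method = "jitter",
                         vertical = FALSE, xlab = "stemness index", ...)
  }
  invisible(x)
}

#' Fit the stemness index independently within each series
#'
#' Refits the principal component inside each dataset (never pooled), so
#' each series is summarized on its own dominant signature axis. Series
#' whose fit fails (for example, below-coverage signatures) are reported
#' as errors in the result without stopping the others.
#'
#' @param series Named list of expression matrices.
#' @param sig Signature gene ids.
#' @param orientation_group,pheno_list Optional orientation: a group label
#'   and a matching named list of phenotype tables. Series without the
#'   group fall back to the loading sign rule, with a message.
#' @return Named list; each element a `stemness` fit or a `try-error`.
#' @export
stemness_per_series <- function(series, sig, orientation_group = NULL,
                                pheno_list = NULL) {
  stopifnot(is.list(series))
  nm <- names(series)
  if (is.null(nm)) nm <- paste0("series", seq_along(series))
  out <- vector("list", length(series))
  names(out) <- nm
  for (i in seq_along(series)) {
    ph <- if (!is.null(pheno_list)) pheno_list[[i]] else NULL
    og <- orientation_group
    if (!is.null(og) && (is.null(ph) || !og %in% ph$group)) {
      message("series '", nm[i], "': orientation group '", og,
              "' absent; using loading sign fallback")
      og <- NULL
    }
    out[[i]] <- try(compute_stemness(series[[i]], sig,
                                     orientation_group = og, pheno = ph),
                    silent = TRUE)
  }
  out
}

#' Separation of an index along an ordered phenotype
#'
#' Orientation-free summary of how well a per-sample scalar recovers an
#' ordered labeling (differentiation stage, tumor grade): absolute
#' Spearman correlation with the level codes, per-level medians, and the
#' pairwise rank-sum AUC matrix folded to >= 0.5.
#'
#' @param index Named or plain numeric vector.
#' @param ordered_labels Ordered factor (or coercible), same length,
#'   >= 2 non-empty levels.
#' @return List with `spearman_rho_abs`, `medians`, `auc` (upper-triangle
#'   filled symmetric matrix), class `ordered_separation`.
#' @export
ordered_separation <- function(index, ordered_labels) {
  lab <- if (is.ordered(ordered_labels)) droplevels(ordered_labels)
         else factor(ordered_labels, ordered = TRUE)
  lab <- droplevels(lab)
  if (nlevels(lab) < 2L) stop("need >= 2 ordered levels")
  if (length(index) != length(lab)) stop("length mismatch")
  rho <- abs(stats::cor(index, as.integer(lab), method = "spearman"))
  meds <- tapply(index, lab, stats::median)
  lv <- levels(lab)
  auc <- matrix(NA_real_, nlevels(lab), nlevels(lab), dimnames = list(lv, lv))
  for (i in seq_len(nlevels(lab) - 1L)) for (j in (i + 1L):nlevels(lab)) {
    hi <- index[lab == lv[j]]; lo <- index[lab == lv[i]]
    a <- rank_sum_auc(hi, lo)
    auc[i, j] <- auc[j, i] <- max(a, 1 - a)   # orientation-free fold
  }
  structure(list(spearman_rho_abs = rho, medians = meds, auc = auc),
            class = "ordered_separation")
}

# P(random draw from `hi` outranks one from `lo`), ties counted half.
rank_sum_auc <- function(hi, lo) {
  r <- rank(c(hi, lo))
  n1 <- length(hi); n2 <- length(lo)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' @export
print.ordered_separation <- function(x, ...) {
  cat("Ordered separation: |Spearman rho| =",
      sprintf("%.3f", x$spearman_rho_abs), "\n")
  cat("Per-level medians:\n"); print(signif(x$medians, 4L))
  cat("Pairwise AUC (folded to >= 0.5):\n"); print(round(x$auc, 3L))
  invisible(x)
}

#' Transfer a signature across species and fit the index
#'
#' Signature gene ids are translated through a one-to-one ortholog map;
#' source genes without a unique mapping, and pairs collapsing onto a
#' shared target, are excluded before fitting. Mapped coverage must be
#' >= 0.5 of the original signature.
#'
#' @param x_target Expression matrix in target-species gene ids.
#' @param sig_source Signature in source-species ids.
#' @param map Named character vector source -> target (see
#'   [ortholog_map()]); re-filtered for bidirectional uniqueness.
#' @param orientation_group,pheno Passed to [compute_stemness()].
#' @return A `stemness` fit on the translated signature, with attributes
#'   `mapped`/`unmapped` giving the source id lists.
#' @export
cross_species_index <- function(x_target, sig_source, map,
                                orientation_group = NULL, pheno = NULL) {
  sig_source <- as.character(sig_source)
  map <- map[!(names(map) %in% names(map)[duplicated(names(map))])]
  map <- map[!(map %in% map[duplicated(map)])]
  mapped_src <- intersect(sig_source, names(map))
  targets <- map[mapped_src]
  # a shared target collapsing two signature genes excludes the pair
  dup <- targets %in% targets[duplicated(targets)]
  mapped_src <- mapped_src[!dup]
  targets <- targets[!dup]
  coverage <- length(mapped_src) / length(sig_source)
  if (coverage < 0.5)
    stop("mapped signature coverage ", signif(coverage, 3L),
         " below 0.5 (", length(mapped_src), " mapped, ",
         length(sig_source) - length(mapped_src), " unmapped)")
  fit <- compute_stemness(x_target, unname(targets),
                          orientation_group = orientation_group, pheno = pheno)
  attr(fit, "mapped") <- mapped_src
  attr(fit, "unmapped") <- setdiff(sig_source, mapped_src)
  fit
}
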