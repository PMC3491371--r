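# Probe-to-gene summarization and per-sample rank normalization.

#' Summarize probe-level intensities to gene level
#'
#' Each gene's value is the arithmetic mean, per sample, of its probes'
#' rows. Probes without a mapping are dropped (count reported). Gene rows
#' are returned in lexicographic order.
#'
#' @param probe_matrix Numeric matrix, probes x samples.
#' @param map Named character vector probe_set_id -> gene_id
#'   (many-to-one allowed), e.g. from [read_probe_gene_map()].
#' @return Gene-level expression matrix.
#' @export
summarize_probes <- function(probe_matrix, map) {
  validate_expression_matrix(probe_matrix)
  probes <- rownames(probe_matrix)
  mapped <- probes[probes %in% names(map)]
  if (!length(mapped)) stop("no probe in the matrix maps to a gene")
  dropped <- length(probes) - length(mapped)
  if (dropped) message("summarize_probes: dropped ", dropped, " unmapped probe(s)")
  genes <- map[mapped]
  sub <- probe_matrix[mapped, , drop = FALSE]
  out <- rowsum(sub, group = genes, reorder = TRUE) /
    as.vector(table(genes)[sort(unique(genes))])
  out <- as.matrix(out)
  validate_expression_matrix(out)
  out
}

#' Rank-normalize each sample of an expression matrix
#'
#' Within each sample (column), values are replaced by fractional ranks
#' r/G, where r is the 1-based rank (ties averaged) and G the feature
#' count, giving values in (0, 1] with the within-sample ordering
#' preserved. Makes intensities comparable across data series.
#'
#' @param x Numeric matrix, features x samples.
#' @return Matrix of the same shape with values in (0, 1].
#' @export
rank_normalize <- function(x) {
  validate_expression_matrix(x)
  G <- nrow(x)
  out <- apply(x, 2L, function(col) rank(col, ties.method = "average") / G)
  if (G == 1L) out <- matrix(out, nrow = 1L)  # apply drops to vector shape
  dimnames(out) <- dimnames(x)
  out
}
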