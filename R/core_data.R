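# Domain containers and plain-text readers/writers.
#
# An expression matrix is a base numeric matrix, features in rows and samples
# in columns, with unique dimnames; a phenotype table is a data.frame keyed by
# sample_id. Validators are exported so downstream functions can assert the
# contracts cheaply.

#' Validate an expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique, non-empty feature ids on rows and sample ids on
#' columns, and all values finite.
#'
#' @param x Numeric matrix, features x samples, with dimnames.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  fid <- rownames(x)
  sid <- colnames(x)
  if (is.null(fid) || is.null(sid))
    stop("expression matrix must have feature (row) and sample (column) names")
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values; complete inputs are required")
  invisible(x)
}

#' Read an expression matrix from a delimited text file
#'
#' First row is the sample header, first column the feature ids, remaining
#' cells numeric. The exact inverse of [write_expression_matrix()].
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A validated numeric matrix (features x samples).
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "")
  if (ncol(df) < 2L) stop("expression file needs a feature column and >=1 sample column")
  fid <- df[[1L]]
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at feature row %d ('%s'), sample column %d ('%s')",
                 bad[1L], fid[bad[1L]], bad[2L], colnames(vals)[bad[2L]]))
  }
  dimnames(num) <- list(fid, colnames(vals))
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to a delimited text file
#'
#' @param x Numeric matrix, features x samples.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param digits Significant digits for formatting (default 15, effectively
#'   lossless for doubles round-tripped through text).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, dialect = c("tsv", "csv"),
                                    digits = 15L) {
  dialect <- match.arg(dialect)
  validate_expression_matrix(x)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(feature_id = rownames(x),
                   signif(x, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample phenotype table
#'
#' Expects columns `sample_id`, `is_anchor`, `group`, and optionally
#' `grade` and `stage` (ordered categoricals). Unknown extra columns are
#' kept but ignored by the package, with a message.
#'
#' @param path TSV file path.
#' @return A data.frame with typed columns; `grade`/`stage` are ordered
#'   factors when present, `NA`-free `is_anchor` logical.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  need <- c("sample_id", "is_anchor", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$is_anchor <- as.logical(df$is_anchor)
  if (anyNA(df$is_anchor)) stop("is_anchor column must be logical (TRUE/FALSE)")
  df$group <- as.character(df$group)
  for (col in c("grade", "stage"))
    if (col %in% names(df))
      df[[col]] <- factor(df[[col]], levels = unique(df[[col]]), ordered = TRUE)
  extra <- setdiff(names(df), c(need, "grade", "stage"))
  if (length(extra))
    message("ignoring unknown phenotype column(s): ", paste(extra, collapse = ", "))
  df
}

#' Write a phenotype table
#'
#' @param pheno Phenotype data.frame as produced by [read_phenotypes()] or
#'   the simulators.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Duplicate members within a set are dropped.
#'
#' @param path GMT file path.
#' @return A named list of character vectors with a `description` attribute
#'   (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty gene-set file: ", path)
  sets <- vector("list", length(lines))
  nm <- desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: expected name, description, >=1 member", i))
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  names(sets) <- nm
  names(desc) <- nm
  attr(sets, "description") <- desc
  sets
}

#' Read a two-column ortholog map, enforcing one-to-one uniqueness
#'
#' Entries whose source or target id occurs more than once are dropped
#' (uniqueness in both directions); the drop count is reported with a
#' message. Filtering is idempotent.
#'
#' @param path Two-column TSV (source, target), no header required; a header
#'   line is detected and skipped if its fields repeat nowhere else.
#' @return Named character vector mapping source id -> target id.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  if (!nrow(df)) stop("empty ortholog file: ", path)
  if (ncol(df) < 2L) stop("ortholog file must have two tab-separated columns")
  ortholog_map(df[[1L]], df[[2L]])
}

#' Build a one-to-one ortholog map from source/target id vectors
#'
#' @param source,target Equal-length character vectors.
#' @return Named character vector (names = retained sources); entries with a
#'   repeated source or repeated target are removed.
#' @export
ortholog_map <- function(source, target) {
  source <- as.character(source); target <- as.character(target)
  stopifnot(length(source) == length(target))
  keep <- !(source %in% source[duplicated(source)]) &
          !(target %in% target[duplicated(target)])
  dropped <- sum(!keep)
  if (dropped)
    message("ortholog map: dropped ", dropped,
            " entr", if (dropped == 1L) "y" else "ies",
            " with non-unique source or target")
  stats::setNames(target[keep], source[keep])
}

#' Read a probe-to-gene map (many probes to one gene allowed)
#'
#' @param path Two-column TSV: probe_set_id, gene_id.
#' @return Named character vector probe -> gene; a probe listed twice is an
#'   error.
#' @export
read_probe_gene_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  if (!nrow(df)) stop("empty probe map file: ", path)
  if (anyDuplicated(df[[1L]]))
    stop("probe mapped to more than one gene: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

# Align a phenotype table to the columns of an expression matrix; the matrix
# may contain extra samples, the phenotypes may not.
align_phenotypes <- function(x, pheno) {
  missing <- setdiff(pheno$sample_id, colnames(x))
  if (length(missing))
    stop("phenotype sample(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x[, pheno$sample_id, drop = FALSE]
}
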