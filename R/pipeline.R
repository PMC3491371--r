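# End-to-end pipeline driver: simulate/load -> normalize -> score -> sweep ->
# select -> stemness -> evaluate, with every intermediate written to a run
# directory and the effective configuration echoed to the run log.

#' Run the full signature-discovery pipeline from a configuration
#'
#' The configuration (YAML file or list) names either a `simulate` block
#' (`kind`: `"landscape"`, `"timecourse"` or `"grades"`, plus generator
#' arguments) or an `inputs` block (`matrix`, `phenotypes`, optional
#' `probe_map` TSV paths), the `anchor_label` group, and optional
#' `sweep`, `signature`, `orientation_group` and `characterize` blocks.
#' All randomness flows from the single top-level `seed`. Every stage's
#' artifact is written to `output_dir`; reruns with the same
#' configuration reproduce the outputs byte for byte.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with the run directory and the in-memory
#'   stage results (`matrix`, `pheno`, `scores`, `sweep`, `signature`,
#'   `stemness`, `separation`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  # validate before any computation
  if (is.null(cfg$anchor_label)) stop("config is missing 'anchor_label'")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs a 'simulate' or an 'inputs' block")
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  dir <- output_dir %||% cfg$output_dir %||% stop("config is missing 'output_dir'")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(dir, "run_log.txt")
  note <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
  cat("pipeline run\n", file = log)
  note("package: stemsig ", as.character(utils::packageVersion("stemsig")))
  note("seed: ", seed)
  note("config: ", yaml::as.yaml(cfg))

  # --- acquire data ------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    simargs <- cfg$simulate
    kind <- simargs$kind %||% "landscape"
    simargs$kind <- NULL
    simargs$seed <- seed
    sim <- switch(kind,
      landscape = simulate_landscape(do.call(landscape_config, simargs)),
      timecourse = do.call(simulate_time_course, simargs),
      grades = do.call(simulate_graded_tumors, simargs),
      stop("unknown simulate kind: ", kind))
    x <- sim$matrix; pheno <- sim$pheno; truth <- sim$truth
    write_expression_matrix(x, file.path(dir, "matrix.tsv"))
    write_phenotypes(pheno, file.path(dir, "phenotypes.tsv"))
    note("stage simulate: ", kind, ", ", nrow(x), " genes x ", ncol(x),
         " samples")
  } else {
    x <- read_expression_matrix(cfg$inputs$matrix)
    pheno <- read_phenotypes(cfg$inputs$phenotypes)
    if (!is.null(cfg$inputs$probe_map)) {
      x <- summarize_probes(x, read_probe_gene_map(cfg$inputs$probe_map))
      note("stage summarize: ", nrow(x), " genes")
    }
  }
  if (cfg$anchor_label %in% pheno$group) {
    pheno$is_anchor <- pheno$group == cfg$anchor_label
  } else if (!any(pheno$is_anchor)) {
    stop("anchor label '", cfg$anchor_label,
         "' matches no group and no is_anchor flags are set")
  }

  # --- normalize ---------------------------------------------------------
  if (isTRUE(cfg$rank_normalize %||% TRUE)) {
    x <- rank_normalize(x)
    write_expression_matrix(x, file.path(dir, "matrix_ranked.tsv"))
    note("stage normalize: rank-normalized ", nrow(x), " genes")
  }

  # --- score -------------------------------------------------------------
  scores <- rank_genes(x, pheno, W = cfg$window %||% "auto")
  utils::write.table(as.data.frame(scores), file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("stage score: W = ", attr(scores, "W"))

  # --- sweep + select ----------------------------------------------------
  sweep_tab <- NULL
  sig_cfg <- cfg$signature %||% list(top_n = min(60L, nrow(scores)))
  orientation <- cfg$orientation_group %||% cfg$anchor_label
  if (!is.null(cfg$sweep)) {
    grid <- as.integer(unlist(cfg$sweep$grid))
    sweep_tab <- threshold_sweep(x, pheno, n_grid = grid,
                                 eval_groups = unlist(cfg$sweep$eval_groups),
                                 orientation_group = orientation,
                                 table = scores)
    utils::write.table(as.data.frame(sweep_tab), file.path(dir, "sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("stage sweep: best n = ", attr(sweep_tab, "best_n"))
    if (identical(sig_cfg, "sweep") || isTRUE(sig_cfg$from_sweep))
      sig_cfg <- list(top_n = attr(sweep_tab, "best_n"))
  }
  sig <- do.call(select_signature, c(list(table = scores), sig_cfg))
  writeLines(unclass(sig), file.path(dir, "signature.txt"))
  note("stage select: ", length(sig), " genes")

  # --- stemness + evaluation --------------------------------------------
  st <- compute_stemness(x, sig, orientation_group = orientation,
                         pheno = pheno)
  idx_tab <- data.frame(sample_id = names(st$index), index = st$index,
                        group = pheno$group[match(names(st$index),
                                                  pheno$sample_id)])
  utils::write.table(idx_tab, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("stage stemness: PC1 variance explained ",
       sprintf("%.3f", st$variance_explained[1L]))
  sep <- NULL
  ord_col <- if ("grade" %in% names(pheno) && !all(is.na(pheno$grade)))
    "grade" else if ("stage" %in% names(pheno)) "stage" else NULL
  if (!is.null(ord_col)) {
    sep <- ordered_separation(st$index[pheno$sample_id], pheno[[ord_col]])
    note("stage evaluate: |rho| vs ", ord_col, " = ",
         sprintf("%.3f", sep$spearman_rho_abs))
  }

  # --- characterize (optional) ------------------------------------------
  char <- NULL
  if (!is.null(cfg$characterize)) {
    cc <- cfg$characterize
    modules <- cluster_signature(x, sig, k = cc$k %||% 4L,
                                 normalization = cc$normalization %||% "zscore")
    utils::write.table(data.frame(gene_id = names(modules),
                                  module = as.integer(modules)),
                       file.path(dir, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    grp_list <- split(pheno$sample_id, pheno$group)
    grp_list <- grp_list[vapply(grp_list, length, 1L) >= 3L]
    cn <- correlation_null(x, sig, grp_list,
                           n_random = cc$n_random %||% 200L, seed = seed)
    shifts <- vapply(cn$groups, `[[`, numeric(1L), "location_shift")
    utils::write.table(data.frame(group = names(shifts),
                                  location_shift = shifts),
                       file.path(dir, "correlation_null.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("stage characterize: ", attr(modules, "k"), " modules")
    char <- list(modules = modules, correlation_null = cn)
  }

  # --- report ------------------------------------------------------------
  rp <- file.path(dir, "report.txt")
  cat("signature size: ", length(sig), "\n",
      "PC1 variance explained: ",
      sprintf("%.3f", st$variance_explained[1L]), "\n",
      if (!is.null(sweep_tab))
        paste0("sweep best n: ", attr(sweep_tab, "best_n"), "\n") else "",
      if (!is.null(sep))
        paste0("|Spearman rho| vs ", ord_col, ": ",
               sprintf("%.3f", sep$spearman_rho_abs), "\n") else "",
      sep = "", file = rp)
  invisible(list(dir = dir, matrix = x, pheno = pheno, truth = truth,
                 scores = scores, sweep = sweep_tab, signature = sig,
                 stemness = st, separation = sep, characterize = char))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
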