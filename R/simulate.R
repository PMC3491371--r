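# Seeded synthetic-data generators with planted ground truth.
#
# The generators emulate the statistical structure the analysis assumes:
# a minority anchor population whose planted "band" genes are tightly
# localized in expression while non-anchor samples spread broadly or
# bimodally around the band; a 1-D latent stemness gradient shared across
# differentiation groups and driving planted "gradient" genes linearly;
# staged time courses; and graded tumor series with diffuse mid-grades.
# Every generator is a pure function of (config, seed).

# Seed the RNG, returning the previous state so callers can restore it.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Configuration for a synthetic expression landscape
#'
#' Defaults describe the reference study landscape: 2,000 genes over 400
#' samples in five differentiation groups with a 10% pluripotent anchor
#' minority, 60 gradient genes driven linearly by the latent stemness
#' `s`, and 60 band genes whose anchor values sit in a narrow intensity
#' band (half of them with symmetric-bimodal non-anchor values straddling
#' the band, so a mean-shift t-test is blind to them). `noise_sd = 0.08`
#' puts the nominal gradient signal-to-noise ratio near 4 given the
#' default group-stemness spread (sd of `s` about 0.32).
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param group_sizes Named integer vector, must sum to `n_samples`.
#' @param group_stemness Named latent means in `[0, 1]`, same names.
#' @param anchor_groups Groups flagged `is_anchor`.
#' @param n_planted_gradient,n_planted_band Planted gene counts.
#' @param band_width Width of the anchor band on the unit intensity
#'   scale, in (0, 1).
#' @param bimodal_fraction Share of band genes with bimodal non-anchors.
#' @param noise_sd Gaussian noise sd added to gradient genes.
#' @param s_jitter Within-group sd of the latent stemness.
#' @param seed Integer seed.
#' @return A `landscape_config` list, validated.
#' @export
landscape_config <- function(n_genes = 2000L, n_samples = 400L,
                             group_sizes = c(pluripotent = 40L,
                                             multipotent = 60L,
                                             progenitor = 60L,
                                             cancer = 120L,
                                             normal = 120L),
                             group_stemness = c(pluripotent = 1,
                                                multipotent = 0.75,
                                                progenitor = 0.55,
                                                cancer = 0.35,
                                                normal = 0.1),
                             anchor_groups = "pluripotent",
                             n_planted_gradient = 60L,
                             n_planted_band = 60L,
                             band_width = 0.1,
                             bimodal_fraction = 0.5,
                             noise_sd = 0.08,
                             s_jitter = 0.05,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              group_sizes = group_sizes, group_stemness = group_stemness,
              anchor_groups = anchor_groups,
              n_planted_gradient = as.integer(n_planted_gradient),
              n_planted_band = as.integer(n_planted_band),
              band_width = band_width, bimodal_fraction = bimodal_fraction,
              noise_sd = noise_sd, s_jitter = s_jitter,
              seed = as.integer(seed))
  if (sum(cfg$group_sizes) != cfg$n_samples)
    stop("group sizes sum to ", sum(cfg$group_sizes), ", not n_samples")
  if (!setequal(names(cfg$group_sizes), names(cfg$group_stemness)))
    stop("group_sizes and group_stemness must name the same groups")
  if (!all(cfg$anchor_groups %in% names(cfg$group_sizes)))
    stop("anchor group(s) not in group_sizes")
  if (cfg$n_planted_gradient + cfg$n_planted_band > cfg$n_genes)
    stop("planted gene counts exceed n_genes")
  if (cfg$band_width <= 0 || cfg$band_width >= 1)
    stop("band_width must lie in (0, 1)")
  if (cfg$bimodal_fraction < 0 || cfg$bimodal_fraction > 1)
    stop("bimodal_fraction must lie in [0, 1]")
  structure(cfg, class = "landscape_config")
}

#' Simulate an expression landscape with planted structure
#'
#' Background genes are iid Gaussian. Gradient genes equal
#' `beta * s + noise` for a per-gene effect `beta ~ U(0.5, 1.5)` and the
#' per-sample latent stemness `s`. Band genes place anchor samples
#' uniformly inside a narrow band and non-anchor samples either uniformly
#' over the full intensity range or in an equal-weight Gaussian mixture
#' with components equidistant from the band center (means matched, so a
#' t contrast between anchors and non-anchors is weak by symmetry).
#'
#' @param cfg A [landscape_config()].
#' @return List with `matrix` (expression matrix), `pheno` (phenotype
#'   data.frame), `truth` (planted gene ids by kind, per-sample latent
#'   `s`, per-gene effects).
#' @export
simulate_landscape <- function(cfg = landscape_config()) {
  stopifnot(inherits(cfg, "landscape_config"))
  rs <- .seeded_rng(cfg$seed)
  on.exit(.restore_rng(rs), add = TRUE)
  S <- cfg$n_samples; G <- cfg$n_genes
  groups <- rep(names(cfg$group_sizes), times = cfg$group_sizes)
  sample_ids <- sprintf("s%04d", seq_len(S))
  s <- cfg$group_stemness[groups] + stats::rnorm(S, 0, cfg$s_jitter)
  names(s) <- sample_ids
  is_anchor <- groups %in% cfg$anchor_groups
  if (!any(is_anchor) && cfg$n_planted_band > 0L)
    stop("band genes require at least one anchor sample")
  gene_ids <- sprintf("g%04d", seq_len(G))
  n_planted <- cfg$n_planted_gradient + cfg$n_planted_band
  planted_idx <- if (n_planted) sample(G, n_planted) else integer(0L)
  grad_idx <- utils::head(planted_idx, cfg$n_planted_gradient)
  band_idx <- utils::tail(planted_idx, cfg$n_planted_band)
  x <- matrix(stats::rnorm(G * S), nrow = G,
              dimnames = list(gene_ids, sample_ids))
  effects <- numeric(0L)
  if (length(grad_idx)) {
    beta <- stats::runif(length(grad_idx), 0.5, 1.5)
    effects <- stats::setNames(beta, gene_ids[grad_idx])
    x[grad_idx, ] <- outer(beta, s) +
      matrix(stats::rnorm(length(grad_idx) * S, 0, cfg$noise_sd),
             nrow = length(grad_idx))
  }
  bimodal <- logical(0L)
  if (length(band_idx)) {
    n_bi <- round(cfg$bimodal_fraction * length(band_idx))
    bimodal <- c(rep(TRUE, n_bi), rep(FALSE, length(band_idx) - n_bi))
    n_anc <- sum(is_anchor); n_non <- sum(!is_anchor)
    for (j in seq_along(band_idx)) {
      ctr <- stats::runif(1L, 0.3, 0.7)
      row <- numeric(S)
      row[is_anchor] <- stats::runif(n_anc, ctr - cfg$band_width / 2,
                                     ctr + cfg$band_width / 2)
      if (bimodal[j]) {
        side <- sample(c(-1, 1), n_non, replace = TRUE)
        row[!is_anchor] <- ctr + side * 0.25 + stats::rnorm(n_non, 0, 0.05)
      } else {
        row[!is_anchor] <- stats::runif(n_non, 0, 1)
      }
      x[band_idx[j], ] <- row
    }
  }
  pheno <- data.frame(sample_id = sample_ids, is_anchor = is_anchor,
                      group = groups, stringsAsFactors = FALSE)
  truth <- list(gradient_genes = gene_ids[grad_idx],
                band_genes = gene_ids[band_idx],
                bimodal_genes = gene_ids[band_idx][bimodal],
                s = s, effects = effects)
  list(matrix = x, pheno = pheno, truth = truth)
}

#' Simulate a staged differentiation time course
#'
#' Emulates a short differentiation experiment: a few ordered stages
#' (e.g. day 0/4/8/14), each with replicate samples, a strictly
#' decreasing latent stemness across stages, and signature genes tracking
#' it linearly. The default noise (`noise_sd = 0.09` against a stage-mean
#' spread with sd about 0.36) corresponds to a signal-to-noise ratio near
#' 4.
#'
#' @param stages Ordered stage labels (>= 2).
#' @param per_stage_n Samples per stage.
#' @param stemness_levels Strictly monotone decreasing latent means, one
#'   per stage.
#' @param n_genes Total genes.
#' @param n_signature Planted gradient (signature) genes.
#' @param noise_sd Per-gene Gaussian noise sd.
#' @param s_jitter Within-stage latent jitter sd.
#' @param seed Integer seed.
#' @return List with `matrix`, `pheno` (with ordered `stage` column;
#'   first-stage samples flagged as anchors), `truth`.
#' @export
simulate_time_course <- function(stages = c("day0", "day4", "day8", "day14"),
                                 per_stage_n = 6L,
                                 stemness_levels = c(1, 0.6, 0.3, 0.05),
                                 n_genes = 500L, n_signature = 60L,
                                 noise_sd = 0.09, s_jitter = 0.03,
                                 seed = 1L) {
  if (length(stages) < 2L) stop("need >= 2 stages")
  if (length(stemness_levels) != length(stages))
    stop("stemness_levels must match stages")
  if (any(diff(stemness_levels) >= 0))
    stop("stemness_levels must be strictly decreasing")
  rs <- .seeded_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  S <- length(stages) * per_stage_n
  stage_vec <- rep(stages, each = per_stage_n)
  sample_ids <- sprintf("t%03d", seq_len(S))
  s <- rep(stemness_levels, each = per_stage_n) + stats::rnorm(S, 0, s_jitter)
  names(s) <- sample_ids
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sig_idx <- sample(n_genes, n_signature)
  x <- matrix(stats::rnorm(n_genes * S), nrow = n_genes,
              dimnames = list(gene_ids, sample_ids))
  beta <- stats::runif(n_signature, 0.5, 1.5)
  x[sig_idx, ] <- outer(beta, s) +
    matrix(stats::rnorm(n_signature * S, 0, noise_sd), nrow = n_signature)
  pheno <- data.frame(sample_id = sample_ids,
                      is_anchor = stage_vec == stages[1L],
                      group = stage_vec,
                      stage = factor(stage_vec, levels = stages,
                                     ordered = TRUE),
                      stringsAsFactors = FALSE)
  truth <- list(gradient_genes = gene_ids[sig_idx], s = s,
                effects = stats::setNames(beta, gene_ids[sig_idx]))
  list(matrix = x, pheno = pheno, truth = truth)
}

#' Simulate a graded tumor series with diffuse mid-grades
#'
#' Latent stemness rises with grade; middle grades receive inflated
#' variance so adjacent-grade distributions overlap, reproducing the
#' clinical pattern that mid-grade tumors are the hardest to classify.
#'
#' @param grades Ordered grade labels (>= 2).
#' @param per_grade_n Samples per grade.
#' @param grade_stemness Strictly increasing latent means, one per grade.
#' @param overlap Base latent sd within a grade.
#' @param mid_inflation Multiplier on `overlap` for the non-extreme
#'   grades (default 2).
#' @param n_genes,n_signature,noise_sd,seed As in
#'   [simulate_time_course()]; default noise corresponds to a
#'   signal-to-noise ratio near 4 for the default grade spread.
#' @return List with `matrix`, `pheno` (ordered `grade` column, no
#'   anchors), `truth`.
#' @export
simulate_graded_tumors <- function(grades = c("I", "II", "III"),
                                   per_grade_n = 20L,
                                   grade_stemness = c(0.2, 0.5, 0.8),
                                   overlap = 0.1, mid_inflation = 2,
                                   n_genes = 500L, n_signature = 60L,
                                   noise_sd = 0.06, seed = 1L) {
  if (length(grades) < 2L) stop("need >= 2 grades")
  if (length(grade_stemness) != length(grades))
    stop("grade_stemness must match grades")
  if (any(diff(grade_stemness) <= 0))
    stop("grade_stemness must be strictly increasing")
  rs <- .seeded_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  ng <- length(grades)
  S <- ng * per_grade_n
  grade_vec <- rep(grades, each = per_grade_n)
  sds <- rep(overlap, ng)
  if (ng > 2L) sds[2:(ng - 1L)] <- overlap * mid_inflation
  sample_ids <- sprintf("u%03d", seq_len(S))
  s <- rep(grade_stemness, each = per_grade_n) +
    stats::rnorm(S, 0, rep(sds, each = per_grade_n))
  names(s) <- sample_ids
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sig_idx <- sample(n_genes, n_signature)
  x <- matrix(stats::rnorm(n_genes * S), nrow = n_genes,
              dimnames = list(gene_ids, sample_ids))
  beta <- stats::runif(n_signature, 0.5, 1.5)
  x[sig_idx, ] <- outer(beta, s) +
    matrix(stats::rnorm(n_signature * S, 0, noise_sd), nrow = n_signature)
  pheno <- data.frame(sample_id = sample_ids,
                      is_anchor = FALSE,
                      group = paste0("grade_", grade_vec),
                      grade = factor(grade_vec, levels = grades,
                                     ordered = TRUE),
                      stringsAsFactors = FALSE)
  truth <- list(gradient_genes = gene_ids[sig_idx], s = s,
                effects = stats::setNames(beta, gene_ids[sig_idx]))
  list(matrix = x, pheno = pheno, truth = truth)
}
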