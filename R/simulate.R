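# synthetic_data: seeded multi-cohort survival-expression simulator with
# planted proportional-hazards effects, plus a synthetic cell-line drug
# panel. Every downstream stage of the package is testable on this output.

#' Simulation configuration
#'
#' @param K Number of cohorts.
#' @param n_per_cohort Sample count per cohort; scalar (recycled) or length-K
#'   vector.
#' @param G Gene count.
#' @param planted Named numeric vector mapping gene id to log hazard ratio
#'   (per SD of expression). Names must be a subset of the simulated gene
#'   ids `g0001 ... g<G>` (or arbitrary ids if `gene_ids` given).
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (scale in the survival time unit, conventionally months).
#' @param censor_target Target censored fraction in `[0, 1)`.
#' @param batch_shift_sd SD of the per-cohort, per-gene additive location
#'   shift (batch effect).
#' @param batch_scale_range Length-2 range of the per-cohort multiplicative
#'   scale factor, e.g. `c(0.8, 1.25)`.
#' @param block_corr Within-block equicorrelation of expression in `[0, 1)`.
#' @param block_size Genes per correlated block.
#' @param gene_ids Optional explicit gene ids (length G).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(K = 10, n_per_cohort = 150, G = 2000,
                       planted = numeric(0),
                       baseline_shape = 1.2, baseline_scale = 24,
                       censor_target = 0.4,
                       batch_shift_sd = 0.5, batch_scale_range = c(0.8, 1.25),
                       block_corr = 0.3, block_size = 10,
                       gene_ids = NULL, seed = 1L) {
  stopifnot(is_count(K), K >= 1, is_count(G), G >= 1)
  n_per_cohort <- rep_len(as.integer(n_per_cohort), K)
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%04d", seq_len(G))
  stopifnot(length(gene_ids) == G, !anyDuplicated(gene_ids))
  if (length(planted)) {
    stopifnot(!is.null(names(planted)), all(is.finite(planted)))
    miss <- setdiff(names(planted), gene_ids)
    if (length(miss)) cs_stop("planted genes not in gene set: %s", paste(miss, collapse = ", "))
  }
  if (!is.numeric(censor_target) || censor_target < 0 || censor_target >= 1)
    cs_stop("censor_target must be in [0, 1)")
  stopifnot(baseline_shape > 0, baseline_scale > 0,
            block_corr >= 0, block_corr < 1,
            length(batch_scale_range) == 2, all(batch_scale_range > 0),
            batch_shift_sd >= 0)
  structure(list(K = as.integer(K), n_per_cohort = n_per_cohort, G = as.integer(G),
                 planted = planted, baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale, censor_target = censor_target,
                 batch_shift_sd = batch_shift_sd, batch_scale_range = batch_scale_range,
                 block_corr = block_corr, block_size = as.integer(block_size),
                 gene_ids = gene_ids, seed = as.integer(seed)),
            class = "sim_config")
}

## Equicorrelated Gaussian blocks: within a block of size b with correlation
## rho, x = sqrt(rho) * z_block + sqrt(1 - rho) * z_gene, which has unit
## variance and pairwise correlation rho.
sim_expression <- function(n, G, block_corr, block_size) {
  block_of <- ((seq_len(G) - 1L) %/% block_size) + 1L
  nblock <- max(block_of)
  zb <- matrix(stats::rnorm(nblock * n), nblock, n)
  zg <- matrix(stats::rnorm(G * n), G, n)
  sqrt(block_corr) * zb[block_of, , drop = FALSE] + sqrt(1 - block_corr) * zg
}

## Uniform(0, c_max) censoring with c_max chosen by bisection so that the
## expected censored fraction, given the drawn event times, hits the target:
## P(C < t) = min(t / c_max, 1).
calibrate_cmax <- function(times, target) {
  if (target <= 0) return(Inf)
  expected_cens <- function(cmax) mean(pmin(times / cmax, 1))
  lo <- min(times) / 2
  hi <- max(times) * 2
  while (expected_cens(hi) > target) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (expected_cens(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a multi-cohort survival-expression dataset
#'
#' Expression is drawn as correlated Gaussian blocks, a per-cohort batch
#' shift/scale is applied, and event times follow a Weibull proportional
#' hazards model on the pre-batch expression:
#' `t = scale * (-log(U) * exp(-lp))^(1/shape)` with
#' `lp = sum_j beta_j x_j` over planted genes. Censoring is independent
#' Uniform(0, c_max), with c_max calibrated by bisection so the realized
#' censored fraction approximates `censor_target`.
#'
#' @param cfg A [sim_config()].
#' @return List with `multicohort` (cohort 1 has role `"training"`, the rest
#'   `"testing"`) and `truth`: list with `planted`, per-cohort true linear
#'   predictors `lp`, and per-cohort `batch` parameters.
#' @export
simulate_multicohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  beta <- stats::setNames(numeric(cfg$G), cfg$gene_ids)
  beta[names(cfg$planted)] <- cfg$planted
  planted_idx <- which(beta != 0)
  cohorts <- vector("list", cfg$K)
  lps <- vector("list", cfg$K)
  batches <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    n <- cfg$n_per_cohort[k]
    x <- sim_expression(n, cfg$G, cfg$block_corr, cfg$block_size)
    # planted (causal) genes are kept independent of the correlated
    # background blocks so every non-planted gene is truly null
    if (length(planted_idx))
      x[planted_idx, ] <- stats::rnorm(length(planted_idx) * n)
    rownames(x) <- cfg$gene_ids
    colnames(x) <- sprintf("c%02d_s%04d", k, seq_len(n))
    lp <- if (length(planted_idx))
      drop(crossprod(x[planted_idx, , drop = FALSE], beta[planted_idx])) else numeric(n)
    u <- stats::runif(n)
    t_event <- cfg$baseline_scale * (-log(u) * exp(-lp))^(1 / cfg$baseline_shape)
    cmax <- calibrate_cmax(t_event, cfg$censor_target)
    t_cens <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    time <- pmax(time, .Machine$double.eps)
    shift <- stats::rnorm(cfg$G, 0, cfg$batch_shift_sd)
    scale <- stats::runif(1, cfg$batch_scale_range[1], cfg$batch_scale_range[2])
    xb <- x * scale + shift
    surv <- data.frame(sample_id = colnames(x), time = time, event = event,
                       stringsAsFactors = FALSE)
    cohorts[[k]] <- cohort(sprintf("sim%02d", k), xb, surv,
                           role = if (k == 1L) "training" else "testing")
    lps[[k]] <- stats::setNames(lp, colnames(x))
    batches[[k]] <- list(shift = shift, scale = scale)
  }
  names(lps) <- names(batches) <- vapply(cohorts, `[[`, "", "name")
  mc <- if (cfg$K >= 2) intersect_genes(cohorts)
        else structure(list(cohorts = stats::setNames(cohorts, cohorts[[1]]$name),
                            shared_genes = cfg$gene_ids),
                       class = "multicohort")
  truth <- list(planted = cfg$planted, lp = lps, batch = batches)
  list(multicohort = mc, truth = truth)
}

#' Simulate a cell-line drug-response panel
#'
#' Builds a cell-line expression matrix and an AUC matrix (lower AUC = more
#' sensitive). For each "sensitive" compound, `AUC = a - b * score + noise`
#' where `score = sum_j w_j x_j` uses `signature_weights`; null compounds get
#' AUC independent of the score. About `missing_frac` of entries are set
#' missing at random.
#'
#' @param n_lines,n_compounds,n_sensitive Panel dimensions; `n_sensitive <=
#'   n_compounds`.
#' @param signature_weights Named numeric vector gene -> weight defining the
#'   score; the expression matrix contains these genes plus `n_extra_genes`
#'   decoys.
#' @param noise_sd SD of the additive AUC noise.
#' @param b Sensitivity slope (AUC units per score unit).
#' @param n_extra_genes Decoy genes carrying no signal.
#' @param missing_frac Fraction of AUC entries set missing.
#' @param seed Integer seed.
#' @return List with `expr` (genes x lines), `auc` (lines x compounds),
#'   `sensitive` (compound ids with planted signal).
#' @export
simulate_drug_panel <- function(n_lines, n_compounds, n_sensitive,
                                signature_weights, noise_sd = 0.1,
                                b = 0.5, n_extra_genes = 50,
                                missing_frac = 0.05, seed = 1L) {
  stopifnot(n_sensitive <= n_compounds, is_count(n_lines), is_count(n_compounds))
  set.seed(as.integer(seed))
  sig_genes <- names(signature_weights)
  genes <- c(sig_genes, sprintf("decoy%04d", seq_len(n_extra_genes)))
  expr <- matrix(stats::rnorm(length(genes) * n_lines), length(genes), n_lines,
                 dimnames = list(genes, sprintf("CL%04d", seq_len(n_lines))))
  score <- drop(crossprod(expr[sig_genes, , drop = FALSE], signature_weights))
  compounds <- sprintf("cmpd%03d", seq_len(n_compounds))
  sensitive <- compounds[seq_len(n_sensitive)]
  auc <- matrix(NA_real_, n_lines, n_compounds,
                dimnames = list(colnames(expr), compounds))
  for (j in seq_len(n_compounds)) {
    base_level <- stats::runif(1, 8, 12)
    auc[, j] <- if (compounds[j] %in% sensitive)
      base_level - b * score + stats::rnorm(n_lines, 0, noise_sd)
    else
      base_level + stats::rnorm(n_lines, 0, noise_sd)
  }
  if (missing_frac > 0) {
    nmiss <- floor(missing_frac * length(auc))
    auc[sample(length(auc), nmiss)] <- NA_real_
  }
  list(expr = expr, auc = auc, sensitive = sensitive)
}

#' Write a simulated multi-cohort dataset to disk
#'
#' Cohorts go out in the package's TSV dialect; the planted truth as a
#' two-column TSV (gene, beta).
#'
#' @param sim Output of [simulate_multicohort()].
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (co in sim$multicohort$cohorts) {
    write_cohort(co,
                 file.path(dir, paste0(co$name, "_expr.tsv")),
                 file.path(dir, paste0(co$name, "_clin.tsv")))
  }
  truth <- data.frame(gene = names(sim$truth$planted),
                      beta = unname(sim$truth$planted))
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Standard synthetic benchmarks
#'
#' Two fixed study conditions used throughout the package's tests and
#' reproduction script: `"screen"` (K = 10 cohorts of n = 150, G = 2000
#' genes, 20 planted genes with |log HR| = 0.5 alternating sign) sized for
#' the consensus screen, and `"sweep"` (K = 10 cohorts of n = 200, G = 500,
#' same planted structure) sized for the combination sweep. Expression
#' carries block correlation 0.3 and cohort batch shift/scale; censoring
#' targets 40%.
#'
#' @param which `"screen"` or `"sweep"`.
#' @param seed Integer seed.
#' @return As [simulate_multicohort()].
#' @export
sim_benchmark <- function(which = c("screen", "sweep"), seed = 1L) {
  which <- match.arg(which)
  G <- if (which == "screen") 2000L else 500L
  n <- if (which == "screen") 150L else 200L
  planted <- stats::setNames(rep_len(c(0.5, -0.5), 20L), sprintf("g%04d", 1:20))
  simulate_multicohort(sim_config(
    K = 10, n_per_cohort = n, G = G, planted = planted,
    censor_target = 0.4, batch_shift_sd = 0.5,
    batch_scale_range = c(0.8, 1.25), block_corr = 0.3, seed = seed))
}
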