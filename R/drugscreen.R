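# drug_screen: ridge transfer of cell-line drug response (AUC, lower = more
# sensitive) onto patient expression, followed by a decile differential
# filter and a Spearman correlation filter whose intersection defines the
# candidate compounds.

#' Drug-screen configuration
#'
#' @param decile_fraction Fraction of patients in each extreme score group
#'   (default 0.10).
#' @param log2fc_threshold Fold-change gate: `log2(mean AUC low-score group /
#'   mean AUC high-score group) > threshold` (default 0.2) selects compounds
#'   with lower AUC (more sensitivity) in the high-score group.
#' @param spearman_threshold Correlation gate: Spearman r between estimated
#'   AUC and score below this (default -0.4; must be negative).
#' @param wilcoxon_alpha Two-sided rank-sum p gate accompanying the fold
#'   change (default 0.05).
#' @param max_missing_fraction Compounds with more missing AUC entries are
#'   dropped (default 0.2).
#' @param ridge_lambda_grid Ridge penalty grid for the transfer model.
#' @param min_lines Minimum observed cell lines per compound (default 10).
#' @param min_gene_overlap Minimum gene overlap between panels (default 100).
#' @param seed Integer seed (cross-validation folds).
#' @return Object of class `drug_screen_config`.
#' @export
drug_screen_config <- function(decile_fraction = 0.10, log2fc_threshold = 0.2,
                               spearman_threshold = -0.4, wilcoxon_alpha = 0.05,
                               max_missing_fraction = 0.2,
                               ridge_lambda_grid = 10^seq(2, -2, length.out = 25),
                               min_lines = 10, min_gene_overlap = 100,
                               seed = 1L) {
  stopifnot(decile_fraction > 0, decile_fraction <= 0.5,
            spearman_threshold < 0, wilcoxon_alpha > 0, wilcoxon_alpha <= 1)
  structure(list(decile_fraction = decile_fraction,
                 log2fc_threshold = log2fc_threshold,
                 spearman_threshold = spearman_threshold,
                 wilcoxon_alpha = wilcoxon_alpha,
                 max_missing_fraction = max_missing_fraction,
                 ridge_lambda_grid = sort(ridge_lambda_grid, decreasing = TRUE),
                 min_lines = as.integer(min_lines),
                 min_gene_overlap = as.integer(min_gene_overlap),
                 seed = as.integer(seed)),
            class = "drug_screen_config")
}

#' Estimate patient drug response by ridge transfer
#'
#' Per compound: genes are standardized on the cell-line panel, AUC is
#' regressed on expression with a ridge penalty chosen by 10-fold
#' cross-validation over the configured grid, and patient expression
#' (standardized with the cell-line parameters) is pushed through the model.
#' Compounds with fewer than `min_lines` observed lines or too many missing
#' entries are excluded with a log entry.
#'
#' @param ccl_expr Cell-line expression, genes x lines.
#' @param auc AUC matrix, lines x compounds (NA = missing).
#' @param patient_expr Patient expression, genes x patients.
#' @param cfg A [drug_screen_config()].
#' @return Matrix patients x retained compounds of estimated AUC.
#' @export
estimate_patient_auc <- function(ccl_expr, auc, patient_expr, cfg = drug_screen_config()) {
  shared <- intersect(rownames(ccl_expr), rownames(patient_expr))
  if (length(shared) == 0) cs_stop("zero gene overlap between panels")
  if (length(shared) < cfg$min_gene_overlap)
    cs_stop("gene overlap %d below minimum %d", length(shared), cfg$min_gene_overlap)
  stopifnot(nrow(auc) == ncol(ccl_expr))
  Xc <- t(ccl_expr[shared, , drop = FALSE])
  mu <- colMeans(Xc)
  sdv <- apply(Xc, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xc <- sweep(sweep(Xc, 2, mu), 2, sdv, "/")
  Xp <- sweep(sweep(t(patient_expr[shared, , drop = FALSE]), 2, mu), 2, sdv, "/")
  keep <- character(0)
  preds <- list()
  set.seed(cfg$seed)
  for (j in colnames(auc)) {
    y <- auc[, j]
    obs <- which(!is.na(y))
    if (length(obs) < cfg$min_lines ||
        mean(is.na(y)) > cfg$max_missing_fraction) {
      cs_log("INFO", "estimate_patient_auc",
             sprintf("compound %s excluded (%d observed lines)", j, length(obs)))
      next
    }
    foldid <- sample(rep_len(seq_len(10), length(obs)))
    cvfit <- glmnet::cv.glmnet(Xc[obs, , drop = FALSE], y[obs], alpha = 0,
                               lambda = cfg$ridge_lambda_grid, foldid = foldid,
                               standardize = FALSE)
    preds[[j]] <- drop(stats::predict(cvfit, newx = Xp, s = "lambda.min"))
    keep <- c(keep, j)
  }
  if (!length(keep)) cs_stop("no compound passed the missingness filter")
  out <- do.call(cbind, preds)
  rownames(out) <- colnames(patient_expr)
  out
}

#' Screen compounds against a signature score
#'
#' Two gates, intersected: (a) differential — the top `decile_fraction` of
#' patients by score form the high group and the bottom fraction the low
#' group; a compound passes when `log2(mean AUC low / mean AUC high) >
#' log2fc_threshold` with a two-sided Wilcoxon rank-sum p below
#' `wilcoxon_alpha`; (b) correlation — Spearman r between estimated AUC and
#' score over all patients below `spearman_threshold`. Scores are in
#' protective orientation (higher = better outcome), so hits are compounds
#' predicted more effective in high-score patients.
#'
#' @param est_auc Patients x compounds estimated AUC
#'   (from [estimate_patient_auc()]).
#' @param scores Signature scores aligned to the rows of `est_auc`
#'   (n >= 20), protective orientation unless `orientation` says otherwise.
#' @param cfg A [drug_screen_config()].
#' @param orientation Orientation of `scores`; risk-oriented scores are
#'   negated internally, so the hit set is invariant to the declared
#'   orientation.
#' @return data.frame: `compound`, `log2fc`, `wilcoxon_p`, `spearman_r`,
#'   `passed_differential`, `passed_correlation`, `hit`; hits sorted first
#'   (by r ascending), then the rest.
#' @export
screen_drugs <- function(est_auc, scores, cfg = drug_screen_config(),
                         orientation = c("higher_is_protective", "higher_is_risk")) {
  orientation <- match.arg(orientation)
  if (orientation == "higher_is_risk") scores <- -scores
  n <- nrow(est_auc)
  stopifnot(length(scores) == n)
  if (n < 20) cs_stop("screen_drugs requires at least 20 patients")
  g <- max(1L, floor(n * cfg$decile_fraction))
  if (g < 5) cs_stop("cohort too small for decile screen")
  ord <- order(scores, decreasing = TRUE)
  hi <- ord[seq_len(g)]
  lo <- ord[seq.int(n - g + 1L, n)]
  res <- do.call(rbind, lapply(colnames(est_auc), function(j) {
    a_hi <- est_auc[hi, j]; a_lo <- est_auc[lo, j]
    a_hi <- a_hi[!is.na(a_hi)]; a_lo <- a_lo[!is.na(a_lo)]
    m_hi <- mean(a_hi); m_lo <- mean(a_lo)
    l2 <- if (isTRUE(m_hi > 0) && isTRUE(m_lo > 0)) log2(m_lo / m_hi) else NA_real_
    p <- if (length(a_hi) && length(a_lo) &&
             (stats::sd(c(a_hi, a_lo)) > 0))
      suppressWarnings(stats::wilcox.test(a_lo, a_hi)$p.value) else 1
    ok <- !is.na(est_auc[, j])
    r <- if (sum(ok) >= 3 && stats::sd(est_auc[ok, j]) > 0)
      stats::cor(est_auc[ok, j], scores[ok], method = "spearman") else NA_real_
    data.frame(compound = j, log2fc = l2, wilcoxon_p = p, spearman_r = r,
               stringsAsFactors = FALSE)
  }))
  res$passed_differential <- !is.na(res$log2fc) &
    res$log2fc > cfg$log2fc_threshold & res$wilcoxon_p < cfg$wilcoxon_alpha
  res$passed_correlation <- !is.na(res$spearman_r) &
    res$spearman_r < cfg$spearman_threshold
  res$hit <- res$passed_differential & res$passed_correlation
  res <- res[order(!res$hit, res$spearman_r), , drop = FALSE]
  rownames(res) <- NULL
  res
}
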