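# learners: ten survival-learning algorithm families behind one uniform
# fit / score / select contract, with 10-fold cross-validated
# hyperparameter tuning against held-out Harrell concordance.

LEARNER_FAMILIES <- c("RSF", "LASSO", "Ridge", "Enet", "GBM", "SurvSVM",
                      "SuperPC", "plsRcox", "CoxBoost", "StepCox")
SELECTOR_FAMILIES <- c("RSF", "LASSO", "CoxBoost", "StepCox")

#' Describe a survival-learning algorithm
#'
#' @param family One of `RSF`, `LASSO`, `Ridge`, `Enet`, `GBM`, `SurvSVM`,
#'   `SuperPC`, `plsRcox`, `CoxBoost`, `StepCox`.
#' @param alpha Elastic-net mixing parameter, required for `Enet`
#'   (in `(0, 1)`).
#' @param direction Stepwise direction for `StepCox`: `"both"`,
#'   `"backward"` or `"forward"`.
#' @param hyper_grid Optional named list overriding the family's default
#'   tuning grid (`CoxBoost`: `M` steps grid and `penalty`; `GBM`:
#'   `nrounds`; `SuperPC`: `k`; `plsRcox`: `ncomp`; `RSF`: `num_trees`;
#'   `SurvSVM`: `cost`).
#' @return Object of class `algorithm_spec` with fields `family`, variant
#'   parameters, `label`, `can_select` (TRUE for RSF, LASSO, CoxBoost,
#'   StepCox), `can_model` (TRUE for all).
#' @export
algorithm_spec <- function(family, alpha = NULL, direction = NULL,
                           hyper_grid = list()) {
  family <- match.arg(family, LEARNER_FAMILIES)
  if (family == "Enet") {
    if (is.null(alpha) || alpha <= 0 || alpha >= 1)
      cs_stop("Enet requires alpha in (0, 1)")
    label <- sprintf("Enet[alpha=%g]", alpha)
  } else if (family == "StepCox") {
    direction <- match.arg(direction, c("both", "backward", "forward"))
    label <- sprintf("StepCox[%s]", direction)
  } else {
    if (!is.null(alpha)) cs_stop("alpha is only meaningful for Enet")
    label <- family
  }
  structure(list(family = family, alpha = alpha, direction = direction,
                 hyper_grid = hyper_grid, label = label,
                 can_select = family %in% SELECTOR_FAMILIES,
                 can_model = TRUE),
            class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf("<algorithm_spec %s%s>\n", x$label,
              if (x$can_select) " (selector)" else ""))
  invisible(x)
}

#' Cross-validation plan
#'
#' @param folds Number of folds (default 10); reduced with a warning when it
#'   exceeds the event count.
#' @param seed Integer seed governing fold assignment and any stochastic
#'   learner internals. The tuning metric is fixed to Harrell's C-index.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(folds = 10, seed = 1L) {
  stopifnot(is_count(folds), folds >= 2)
  structure(list(folds = as.integer(folds), seed = as.integer(seed),
                 metric = "harrell_cindex"),
            class = "cv_plan")
}

## Random fold assignment; shrinks the fold count to the event count if
## needed so every fold can contain an event.
make_folds <- function(n, n_events, cv) {
  folds <- cv$folds
  if (folds > n_events) {
    cs_log("WARNING", "cv", sprintf("folds reduced from %d to %d (event count)",
                                    folds, n_events))
    folds <- max(2L, n_events)
  }
  set.seed(derive_seed(cv$seed, "folds"))
  sample(rep_len(seq_len(folds), n))
}

## Generic grid tuner. fit_fun(X, surv, idx_train) -> model;
## score_fun(model, X, idx_test, grid_entry) -> held-out risk scores.
## Grid must be ordered by increasing complexity; ties in mean out-of-fold
## C-index go to the earliest (least complex) entry.
cv_tune <- function(X, surv, fold_id, grid, fit_fun, score_fun) {
  nf <- max(fold_id)
  cmat <- matrix(NA_real_, nf, length(grid))
  for (f in seq_len(nf)) {
    tr <- fold_id != f
    te <- !tr
    model <- tryCatch(fit_fun(X[tr, , drop = FALSE], surv[tr, , drop = FALSE]),
                      error = function(e) NULL)
    if (is.null(model)) next
    for (gi in seq_along(grid)) {
      sc <- tryCatch(score_fun(model, X[te, , drop = FALSE], grid[[gi]]),
                     error = function(e) NULL)
      if (is.null(sc)) next
      cmat[f, gi] <- cindex_quick(sc, surv$time[te], surv$event[te])
    }
  }
  mean_c <- colMeans(cmat, na.rm = TRUE)
  mean_c[is.nan(mean_c)] <- -Inf
  if (all(!is.finite(mean_c))) cs_stop("cv_tune: no grid entry produced a valid fit")
  best <- which(mean_c == max(mean_c))[1]
  list(best = best, mean_c = mean_c, per_fold = cmat)
}

#' Fit a survival learner with cross-validated tuning
#'
#' Dispatches to the family implementation; hyperparameters (where the
#' family has any) are chosen by maximizing the mean out-of-fold C-index,
#' ties going to the least complex grid entry, and the final model is refit
#' on the full training cohort. All families consume cohort-standardized
#' expression, so linear coefficients are per expression SD.
#'
#' @param spec An [algorithm_spec()].
#' @param train A standardized training `cohort`.
#' @param cv A [cv_plan()].
#' @return Object of class `fitted_learner`: `spec`, `genes_used`,
#'   `selected_genes` (selectors only; ordered by decreasing
#'   importance/|coefficient|, ties by gene id), `orientation`, `params`
#'   (family internals), `cv_record`.
#' @export
fit_learner <- function(spec, train, cv = cv_plan()) {
  stopifnot(inherits(spec, "algorithm_spec"), inherits(train, "cohort"),
            inherits(cv, "cv_plan"))
  X <- t(train$expr)                      # samples x genes
  surv <- train$surv
  n_events <- sum(surv$event)
  fold_id <- make_folds(nrow(X), n_events, cv)
  set.seed(derive_seed(cv$seed, spec$label))
  fitted <- switch(spec$family,
    LASSO   = fit_penalized(spec, X, surv, fold_id, alpha = 1),
    Ridge   = fit_penalized(spec, X, surv, fold_id, alpha = 0),
    Enet    = fit_penalized(spec, X, surv, fold_id, alpha = spec$alpha),
    CoxBoost = fit_coxboost(spec, X, surv, fold_id),
    StepCox = fit_stepcox(spec, X, surv),
    RSF     = fit_rsf(spec, X, surv, cv),
    GBM     = fit_gbm(spec, X, surv, fold_id, cv),
    SurvSVM = fit_survsvm(spec, X, surv),
    SuperPC = fit_superpc(spec, X, surv, fold_id),
    plsRcox = fit_plsrcox(spec, X, surv, fold_id)
  )
  fitted$spec <- spec
  fitted$genes_used <- colnames(X)
  class(fitted) <- "fitted_learner"
  fitted
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat(sprintf("<fitted_learner %s: %d genes in, %s, orientation=%s>\n",
              x$spec$label, length(x$genes_used),
              if (x$spec$can_select)
                sprintf("%d selected", length(x$selected_genes)) else "modeler",
              x$orientation))
  invisible(x)
}

## order a named importance/coefficient vector: decreasing magnitude,
## ties broken lexicographically by gene id
order_selected <- function(values) {
  nz <- values[values != 0 & !is.na(values)]
  if (!length(nz)) return(character(0))
  names(nz)[order(-abs(nz), names(nz), method = "radix")]
}

#' Predict per-sample scores from a fitted learner
#'
#' Deterministic; the declared orientation is passed through unchanged.
#'
#' @param fl A `fitted_learner`.
#' @param expr Expression matrix (genes x samples) or a `cohort`; must
#'   contain every gene the learner consumes.
#' @return Named numeric scores with attribute `orientation`.
#' @export
predict_scores <- function(fl, expr) {
  stopifnot(inherits(fl, "fitted_learner"))
  if (inherits(expr, "cohort")) expr <- expr$expr
  need <- fl$genes_used
  missing <- setdiff(need, rownames(expr))
  if (length(missing))
    cs_stop("expression is missing required gene(s): %s", paste(missing, collapse = ", "))
  X <- t(expr[need, , drop = FALSE])
  sc <- predict_family(fl, X)
  names(sc) <- colnames(expr)
  attr(sc, "orientation") <- fl$orientation
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genes retained by a selector
#'
#' @param fl A `fitted_learner` whose family can select (RSF, LASSO,
#'   CoxBoost, StepCox).
#' @return Gene ids ordered by decreasing importance/|coefficient|, ties by
#'   gene id.
#' @export
select_features <- function(fl) {
  stopifnot(inherits(fl, "fitted_learner"))
  if (!fl$spec$can_select)
    cs_stop("%s is not a selector", fl$spec$label)
  if (length(fl$selected_genes) == 0)
    cs_stop("selector returned no genes")
  fl$selected_genes
}

## risk-oriented copy of a score vector
as_risk <- function(scores, orientation = attr(scores, "orientation")) {
  if (identical(orientation, "higher_is_protective")) -as.numeric(scores)
  else as.numeric(scores)
}
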