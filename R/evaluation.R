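# evaluation: survival model evaluation suite. Harrell C-index with a
# paired jackknife z-comparison, IPCW cumulative/dynamic time-dependent AUC
# with Kaplan-Meier censoring weights, KM curves + log-rank test,
# calibration curves, and application of externally published gene
# signatures.

## Pairwise contribution matrices underlying the C-index. A pair (i, j) is
## usable iff the strictly smaller time is an event; pairs with tied times
## are unusable. Returns symmetric matrices counting each unordered pair in
## the upper triangle only.
cindex_pairs <- function(scores, time, event) {
  n <- length(scores)
  dt <- outer(time, time, "<")              # dt[i,j]: t_i < t_j
  usable <- (dt & event == 1) | (t(dt) & matrix(event == 1, n, n, byrow = TRUE))
  usable[lower.tri(usable, diag = TRUE)] <- FALSE
  # concordance: the earlier (event) sample should have the higher risk score
  ds <- outer(scores, scores, "-")
  early_i <- dt & event == 1                # i is the early event of pair (i,j)
  conc <- matrix(0, n, n)
  conc[early_i & ds > 0] <- 1
  conc[early_i & ds == 0] <- 0.5
  early_j <- t(dt) & matrix(event == 1, n, n, byrow = TRUE)  # j early
  conc[early_j & ds < 0] <- 1
  conc[early_j & ds == 0] <- 0.5
  conc[!usable] <- 0
  list(usable = usable, conc = conc)
}

#' Harrell concordance index
#'
#' `C = (concordant + 0.5 * score-ties) / usable pairs`, where a pair is
#' usable iff its strictly smaller observed time is an event (pairs with
#' tied observed times are unusable). Scores must be in risk orientation
#' (higher score = shorter expected survival).
#'
#' @param scores Numeric risk scores.
#' @param surv data.frame with `time` and `event` aligned with `scores`.
#' @return List with `cindex`, `se` (pair-count asymptotic estimator
#'   `sqrt(C(1-C)/pairs)`), `n_pairs`.
#' @export
harrell_cindex <- function(scores, surv) {
  stopifnot(length(scores) == nrow(surv))
  pr <- cindex_pairs(scores, surv$time, surv$event)
  npairs <- sum(pr$usable)
  if (npairs == 0) cs_stop("harrell_cindex: no usable pairs (all censored?)")
  C <- sum(pr$conc) / npairs
  list(cindex = C, se = sqrt(C * (1 - C) / npairs), n_pairs = npairs)
}

## bare-number variant used in tuning loops; NA instead of error
cindex_quick <- function(scores, time, event) {
  pr <- cindex_pairs(scores, time, event)
  npairs <- sum(pr$usable)
  if (npairs == 0) return(NA_real_)
  sum(pr$conc) / npairs
}

#' Compare two C-indexes on the same samples
#'
#' Paired difference `dC = C(A) - C(B)` with leave-one-out jackknife
#' variance; `z = dC / SE`, two-sided normal p-value.
#'
#' @param scoresA,scoresB Risk scores aligned to `surv`.
#' @param surv Survival data.frame (`time`, `event`).
#' @return List with `delta`, `z`, `p`, `cindexA`, `cindexB`.
#' @export
compare_cindex <- function(scoresA, scoresB, surv) {
  n <- nrow(surv)
  stopifnot(length(scoresA) == n, length(scoresB) == n)
  pA <- cindex_pairs(scoresA, surv$time, surv$event)
  pB <- cindex_pairs(scoresB, surv$time, surv$event)
  den <- sum(pA$usable)
  if (den == 0) cs_stop("compare_cindex: no usable pairs")
  numA <- sum(pA$conc); numB <- sum(pB$conc)
  CA <- numA / den; CB <- numB / den
  # leave-one-out: drop all pairs involving sample i (symmetrize triangles)
  pairs_i <- rowSums(pA$usable) + colSums(pA$usable)
  concA_i <- rowSums(pA$conc) + colSums(pA$conc)
  concB_i <- rowSums(pB$conc) + colSums(pB$conc)
  den_i <- den - pairs_i
  ok <- den_i > 0
  dC_i <- (numA - concA_i[ok]) / den_i[ok] - (numB - concB_i[ok]) / den_i[ok]
  m <- length(dC_i)
  jk_var <- (m - 1) / m * sum((dC_i - mean(dC_i))^2)
  delta <- CA - CB
  se <- sqrt(jk_var)
  if (!is.finite(se) || se == 0) {
    if (delta != 0)
      cs_log("WARNING", "compare_cindex", "degenerate jackknife variance; p set to 1")
    return(list(delta = delta, z = 0, p = 1, cindexA = CA, cindexB = CB))
  }
  z <- delta / se
  list(delta = delta, z = z, p = 2 * stats::pnorm(-abs(z)),
       cindexA = CA, cindexB = CB)
}

## Kaplan-Meier of the censoring distribution; returns a function G(t) and
## its left limit G(t-). Reverse KM: censorings are the "events".
censor_km <- function(time, event) {
  ord <- order(time)
  ts <- time[ord]; cs <- 1 - event[ord]
  ut <- unique(ts)
  n_at <- vapply(ut, function(u) sum(ts >= u), 0)
  c_at <- vapply(ut, function(u) sum(cs[ts == u]), 0)
  surv <- cumprod(1 - c_at / n_at)
  list(
    at = function(t) c(1, surv)[findInterval(t, ut) + 1L],
    at_left = function(t) c(1, surv)[findInterval(t, ut, left.open = TRUE) + 1L]
  )
}

#' IPCW time-dependent AUC (cumulative cases / dynamic controls)
#'
#' At horizon `t`, cases are samples with event time `<= t` and `event = 1`,
#' weighted by the inverse Kaplan-Meier censoring survival `1/G(T_i-)`;
#' controls are samples with observed time `> t`. AUC(t) is the weighted
#' probability that a case outranks a control (score ties count 0.5). With
#' no censoring this reduces exactly to the empirical ROC AUC of the binary
#' label `T <= t`.
#'
#' @param scores Risk scores (higher = earlier event).
#' @param surv Survival data.frame.
#' @param horizons Evaluation times, each below the largest observed time.
#' @return data.frame with `horizon`, `auc` (NA when a horizon has no cases
#'   or no controls, with `defined = FALSE`), `n_cases`, `n_controls`.
#' @export
time_auc <- function(scores, surv, horizons) {
  stopifnot(length(scores) == nrow(surv))
  if (any(horizons >= max(surv$time)))
    cs_stop("time_auc: horizons must lie below the largest observed time")
  G <- censor_km(surv$time, surv$event)
  out <- data.frame(horizon = horizons, auc = NA_real_,
                    n_cases = 0L, n_controls = 0L, defined = FALSE)
  for (i in seq_along(horizons)) {
    t0 <- horizons[i]
    case <- surv$time <= t0 & surv$event == 1
    ctrl <- surv$time > t0
    out$n_cases[i] <- sum(case); out$n_controls[i] <- sum(ctrl)
    if (!any(case) || !any(ctrl)) {
      cs_log("WARNING", "time_auc",
             sprintf("horizon %g has no cases or no controls; AUC undefined", t0))
      next
    }
    wi <- 1 / G$at_left(surv$time[case])
    wi[!is.finite(wi)] <- 0
    sc <- scores[case]; st <- scores[ctrl]
    cmp <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
    num <- sum(wi * rowSums(cmp))
    den <- sum(wi) * length(st)
    out$auc[i] <- num / den
    out$defined[i] <- TRUE
  }
  out
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit estimates per group plus the k-group log-rank chi-square
#' statistic (hypergeometric moments at each distinct event time).
#'
#' @param groups Group labels (>= 2 non-empty groups).
#' @param surv Survival data.frame.
#' @return List with `curves` (data.frame: group, time, n_risk, n_event,
#'   surv), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(groups, surv) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) cs_stop("km_logrank: need at least 2 groups")
  if (any(table(groups) == 0)) cs_stop("km_logrank: empty group")
  sf <- survival::survfit(survival::Surv(surv$time, surv$event) ~ groups)
  glab <- rep(sub("^groups=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = glab, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv)
  # log-rank by direct hypergeometric accumulation
  k <- nlevels(groups)
  ut <- sort(unique(surv$time[surv$event == 1]))
  OE <- numeric(k)
  V <- matrix(0, k, k)
  for (t0 in ut) {
    at <- surv$time >= t0
    n <- sum(at)
    d <- sum(surv$event == 1 & surv$time == t0)
    ng <- vapply(levels(groups), function(g) sum(at & groups == g), 0)
    dg <- vapply(levels(groups),
                 function(g) sum(surv$event == 1 & surv$time == t0 & groups == g), 0)
    OE <- OE + dg - ng * d / n
    if (n > 1)
      V <- V + d * (n - d) / (n^2 * (n - 1)) * (diag(ng) * n - outer(ng, ng))
  }
  idx <- seq_len(k - 1)
  Vi <- tryCatch(solve(V[idx, idx, drop = FALSE]), error = function(e) NULL)
  chisq <- if (is.null(Vi)) 0 else drop(t(OE[idx]) %*% Vi %*% OE[idx])
  list(curves = curves, chisq = chisq, df = k - 1,
       p = stats::pchisq(chisq, k - 1, lower.tail = FALSE))
}

#' Calibration curve of predicted survival probabilities
#'
#' Samples are binned by quantiles of the predicted probability of surviving
#' past `t`; within each bin the observed survival is the Kaplan-Meier
#' estimate at `t` with a Greenwood (log-transformed) confidence interval.
#'
#' @param sig_probs Predicted survival probabilities at `t`, in `[0, 1]`.
#' @param surv Survival data.frame.
#' @param t Horizon (below max follow-up).
#' @param n_bins Number of quantile bins (default 4).
#' @return data.frame: `bin`, `n`, `mean_predicted`, `observed`, `lower`,
#'   `upper`, `defined`.
#' @export
calibration_curve <- function(sig_probs, surv, t, n_bins = 4) {
  stopifnot(all(sig_probs >= 0 & sig_probs <= 1), t < max(surv$time))
  qs <- unique(stats::quantile(sig_probs, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 2) {
    bins <- factor(rep(1, length(sig_probs)))
    cs_log("WARNING", "calibration_curve", "constant predictions; single bin used")
  } else {
    bins <- cut(sig_probs, qs, include.lowest = TRUE, labels = FALSE)
    bins <- factor(bins)
  }
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- bins == b
    sf <- survival::survfit(survival::Surv(surv$time[sel], surv$event[sel]) ~ 1,
                            conf.type = "log")
    sm <- summary(sf, times = t, extend = TRUE)
    obs <- sm$surv
    defined <- length(obs) == 1 && is.finite(obs) && (sm$n.risk > 0 || any(surv$time[sel] >= t))
    data.frame(bin = as.integer(b), n = sum(sel),
               mean_predicted = mean(sig_probs[sel]),
               observed = if (length(obs)) obs else NA_real_,
               lower = if (length(sm$lower)) sm$lower else NA_real_,
               upper = if (length(sm$upper)) sm$upper else NA_real_,
               defined = defined)
  }))
  rownames(out) <- NULL
  out
}

#' Define an external published signature
#'
#' @param name Signature name.
#' @param coefficients Named numeric vector gene -> coefficient.
#' @param orientation `"higher_is_risk"` (convention for published risk
#'   scores) or `"higher_is_protective"`.
#' @return Object of class `external_signature`.
#' @export
external_signature <- function(name, coefficients,
                               orientation = c("higher_is_risk", "higher_is_protective")) {
  stopifnot(length(coefficients) >= 1, !is.null(names(coefficients)),
            all(is.finite(coefficients)))
  structure(list(name = name, coefficients = coefficients,
                 orientation = match.arg(orientation)),
            class = "external_signature")
}

#' Apply an external signature to a cohort
#'
#' Risk score `sum_{genes present} coef_g * expr_g`. Missing genes are
#' dropped (default) or raise an error, per `missing_policy`; the coverage
#' is reported in the `coverage` attribute.
#'
#' @param sig An [external_signature()].
#' @param cohort A `cohort`.
#' @param missing_policy `"drop"` or `"error"`.
#' @return Named numeric score vector with attribute `coverage` (list:
#'   `n_used`, `n_total`, `fraction`, `missing`).
#' @export
apply_signature <- function(sig, cohort, missing_policy = c("drop", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(sig, "external_signature"), inherits(cohort, "cohort"))
  genes <- names(sig$coefficients)
  present <- genes[genes %in% rownames(cohort$expr)]
  missing <- setdiff(genes, present)
  if (length(missing) && missing_policy == "error")
    cs_stop("signature '%s': missing gene(s): %s", sig$name, paste(missing, collapse = ", "))
  if (length(present) == 0)
    cs_stop("signature '%s': no signature genes present in cohort", sig$name)
  score <- drop(crossprod(cohort$expr[present, , drop = FALSE], sig$coefficients[present]))
  attr(score, "coverage") <- list(n_used = length(present), n_total = length(genes),
                                  fraction = length(present) / length(genes),
                                  missing = missing)
  score
}

#' Full evaluation report for a score on one cohort
#'
#' Combines the suite: C-index, time-dependent AUC at the requested
#' horizons, median-split KM/log-rank, calibration (via a univariate Cox of
#' outcome on the score plus the Breslow baseline — absolute probabilities
#' are model-derived, not learner-native), and a multivariate Cox of the
#' score adjusted for covariates (categorical covariates one-hot encoded,
#' first level reference).
#'
#' @param scores Risk-oriented scores aligned with the cohort samples.
#' @param cohort A `cohort`.
#' @param horizons AUC/calibration horizons.
#' @param covariates Optional character vector of covariate columns in the
#'   cohort's survival table for the adjusted model.
#' @return List of class `evaluation_report`.
#' @export
evaluate_scores <- function(scores, cohort, horizons = NULL, covariates = NULL) {
  surv <- cohort$surv
  ci <- harrell_cindex(scores, surv)
  auc <- if (length(horizons)) time_auc(scores, surv, horizons) else NULL
  grp <- ifelse(scores >= stats::median(scores), "high_risk", "low_risk")
  lr <- if (length(unique(grp)) == 2) km_logrank(grp, surv) else NULL
  sc_mat <- matrix(scores, ncol = 1, dimnames = list(NULL, "score"))
  cal <- NULL
  cal_fit <- tryCatch(fit_cox(sc_mat, surv), error = function(e) NULL)
  if (!is.null(cal_fit) && cal_fit$converged && length(horizons)) {
    bs <- baseline_survival(cal_fit, sc_mat, surv)
    cal <- lapply(horizons[horizons < max(surv$time)], function(t0) {
      pr <- drop(predict_survival(cal_fit, bs, sc_mat, t0))
      calibration_curve(pr, surv, t0)
    })
    names(cal) <- paste0("t", horizons[horizons < max(surv$time)])
  }
  adj <- NULL
  if (length(covariates)) {
    miss <- setdiff(covariates, names(surv))
    if (length(miss)) cs_stop("covariates not in survival table: %s", paste(miss, collapse = ", "))
    mm <- stats::model.matrix(~ ., data = surv[, covariates, drop = FALSE])[, -1, drop = FALSE]
    adj <- fit_cox(cbind(sc_mat, mm), surv)
  }
  structure(list(cohort = cohort$name, cindex = ci, auc = auc, logrank = lr,
                 calibration = cal, adjusted = adj),
            class = "evaluation_report")
}
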