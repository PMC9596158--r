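# cox_core: Cox proportional-hazards machinery. Newton-Raphson maximization
# of the partial likelihood with Efron (default) or Breslow tie handling,
# the cross-cohort consensus prognostic-gene screen, and the Breslow
# baseline survival needed for calibration.

## Precompute the sorted tie-group structure used by the partial-likelihood
## evaluations. Risk set at an event time t is {j : t_j >= t}; deaths at t
## precede censorings at t.
cox_structure <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) cs_stop("Cox fit requires at least one event")
  ord <- order(time)
  ts <- time[ord]
  es <- event[ord]
  # first sorted position of each unique time, and events per unique time
  first <- which(!duplicated(ts))
  ut <- ts[first]
  gid <- findInterval(ts, ut)
  d <- as.vector(rowsum(es, gid))
  eg <- which(d > 0)
  ev_pos <- which(es == 1)
  # sorted positions of the events in each event group (needed for Efron)
  grp_events <- split(ev_pos, gid[ev_pos])
  list(ord = ord, time = ts, event = es, first = first, ut = ut, d = d,
       event_groups = eg, ev_pos = ev_pos, grp_events = grp_events,
       has_ties = any(d[eg] > 1), n = length(ts), n_events = sum(es))
}

## reverse cumulative sums by column: out[i, ] = colSums over rows >= i
revcumsum <- function(m) {
  if (is.null(dim(m))) return(rev(cumsum(rev(m))))
  n <- nrow(m)
  apply(m[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
}

## Partial log-likelihood, gradient, and Hessian at beta for sorted data.
## X: n x p matrix in sorted order. Returns list(loglik, U, H).
cox_lgh <- function(X, st, beta, ties = "efron") {
  n <- st$n; p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)              # guard exp overflow; cancels in ratios
  w <- exp(eta)
  wX <- X * w
  lt1 <- rep(seq_len(p), seq_len(p))                  # lower-triangle index pairs
  lt2 <- unlist(lapply(seq_len(p), seq_len))
  wXX <- wX[, lt1, drop = FALSE] * X[, lt2, drop = FALSE]
  rc_w <- revcumsum(w)
  rc_wX <- revcumsum(wX)
  rc_wXX <- revcumsum(wXX)
  eg <- st$event_groups
  fe <- st$first[eg]
  d <- st$d[eg]
  S0 <- rc_w[fe]
  S1 <- rc_wX[fe, , drop = FALSE]
  S2 <- rc_wXX[fe, , drop = FALSE]
  m1 <- S1 / S0
  # Breslow contributions, fully vectorized over event-time groups
  ll <- sum(eta[st$ev_pos]) - sum(d * log(S0))
  U <- colSums(X[st$ev_pos, , drop = FALSE]) - colSums(d * m1)
  Hflat <- colSums(d * (S2 / S0 - m1[, lt1, drop = FALSE] * m1[, lt2, drop = FALSE]))
  if (ties == "efron" && st$has_ties) {
    # replace the Breslow term of each tied group by the Efron sum
    tied <- which(d > 1)
    for (ti in tied) {
      in_grp <- st$grp_events[[as.character(eg[ti])]]
      dk <- d[ti]
      wd <- sum(w[in_grp])
      S1d <- colSums(wX[in_grp, , drop = FALSE])
      S2d <- colSums(wXX[in_grp, , drop = FALSE])
      ll <- ll + dk * log(S0[ti])
      U <- U + dk * m1[ti, ]
      Hflat <- Hflat - dk * (S2[ti, ] / S0[ti] - m1[ti, lt1] * m1[ti, lt2])
      for (l in 0:(dk - 1)) {
        f <- l / dk
        den <- S0[ti] - f * wd
        mm <- (S1[ti, ] - f * S1d) / den
        ll <- ll - log(den)
        U <- U - mm
        Hflat <- Hflat + (S2[ti, ] - f * S2d) / den - mm[lt1] * mm[lt2]
      }
    }
  }
  H <- matrix(0, p, p)
  H[cbind(lt1, lt2)] <- Hflat
  H[cbind(lt2, lt1)] <- Hflat
  list(loglik = ll, U = U, H = H)
}

## Newton-Raphson with step-halving on presorted data.
cox_newton <- function(X, st, ties = "efron", max_iter = 50, tol = 1e-8,
                       beta_cap = 20) {
  p <- ncol(X)
  beta <- numeric(p)
  cur <- cox_lgh(X, st, beta, ties)
  null_loglik <- cur$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$H, cur$U), error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (h in 0:12) {
      cand <- beta + step / 2^h
      nxt <- cox_lgh(X, st, cand, ties)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) {
        beta <- cand; cur <- nxt; ok <- TRUE; break
      }
    }
    if (!ok) break
    if (any(abs(beta) > beta_cap)) break
  }
  if (max(abs(cur$U)) < tol) converged <- TRUE
  if (any(abs(beta) > beta_cap)) {
    beta <- pmin(pmax(beta, -beta_cap), beta_cap)
    cur <- cox_lgh(X, st, beta, ties)
    converged <- FALSE
  }
  vr <- tryCatch(solve(cur$H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vr), 0))
  list(beta = beta, se = se, loglik = cur$loglik, null_loglik = null_loglik,
       converged = converged, imat = cur$H)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with step-halving;
#' Efron tie handling by default, Breslow available. Convergence when the
#' gradient max-norm falls below `1e-8` or after 50 iterations. Under
#' separation (monotone likelihood) coefficients are capped at `|beta| <= 20`
#' and `converged` is `FALSE` with a warning.
#'
#' @param covariates Numeric matrix or data.frame, samples x p (p >= 1),
#'   finite values.
#' @param surv data.frame with columns `time` (> 0) and `event` (0/1),
#'   aligned row-wise with `covariates`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: `beta`, `se`, `hr = exp(beta)`,
#'   `wald_p` (chi-square on `(beta/se)^2`), `loglik`, `null_loglik`,
#'   `ties`, `converged`, `n`, `n_events`.
#' @export
fit_cox <- function(covariates, surv, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) cs_stop("fit_cox: covariates must be finite")
  stopifnot(nrow(X) == nrow(surv), ncol(X) >= 1)
  st <- cox_structure(surv$time, surv$event)
  Xs <- X[st$ord, , drop = FALSE]
  res <- cox_newton(Xs, st, ties = ties)
  if (!res$converged)
    cs_log("WARNING", "fit_cox",
           "did not converge (possible separation); coefficients capped")
  z2 <- (res$beta / res$se)^2
  wald_p <- stats::pchisq(z2, df = 1, lower.tail = FALSE)
  structure(list(beta = stats::setNames(res$beta, colnames(X)),
                 se = stats::setNames(res$se, colnames(X)),
                 hr = stats::setNames(exp(res$beta), colnames(X)),
                 wald_p = stats::setNames(wald_p, colnames(X)),
                 loglik = res$loglik, null_loglik = res$null_loglik,
                 ties = ties, converged = res$converged,
                 n = st$n, n_events = st$n_events),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit: n=%d, events=%d, ties=%s, converged=%s>\n",
              x$n, x$n_events, x$ties, x$converged))
  print(data.frame(beta = x$beta, se = x$se, HR = x$hr, p = x$wald_p))
  invisible(x)
}

#' Breslow baseline survival of a fitted Cox model
#'
#' Cumulative baseline hazard `Lambda0(t) = sum_{event times u <= t} d_u /
#' S0(u)` with `S0(u) = sum_{j at risk} exp(lp_j)`; `S0(t) = exp(-Lambda0)`.
#' Survival for a sample with linear predictor `lp` is `S0(t)^exp(lp)`.
#'
#' @param fit A converged `cox_fit`.
#' @param covariates,surv The data the model was fitted on.
#' @return Object of class `breslow_baseline` with `time` (sorted event
#'   times), `cumhaz`, `surv`; evaluate with [predict_survival()] or
#'   `s0_at()`.
#' @export
baseline_survival <- function(fit, covariates, surv) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) cs_stop("baseline_survival requires a converged fit")
  X <- as.matrix(covariates)
  st <- cox_structure(surv$time, surv$event)
  eta <- drop(X[st$ord, , drop = FALSE] %*% fit$beta)
  w <- exp(eta)
  rc_w <- rev(cumsum(rev(w)))
  eg <- st$event_groups
  S0 <- rc_w[st$first[eg]]
  dh <- st$d[eg] / S0
  structure(list(time = st$ut[eg], cumhaz = cumsum(dh),
                 surv = exp(-cumsum(dh))),
            class = "breslow_baseline")
}

#' Evaluate baseline survival S0 at given times
#'
#' Right-continuous step function; `S0(t) = 1` before the first event time.
#'
#' @param bs A `breslow_baseline`.
#' @param times Evaluation times.
#' @return Numeric vector of baseline survival probabilities.
#' @export
s0_at <- function(bs, times) {
  stopifnot(inherits(bs, "breslow_baseline"))
  idx <- findInterval(times, bs$time)
  c(1, bs$surv)[idx + 1L]
}

#' Predicted survival probabilities from a Cox fit
#'
#' `S(t | x) = S0(t)^exp(lp(x))`.
#'
#' @param fit A `cox_fit`.
#' @param bs Its `breslow_baseline`.
#' @param covariates Matrix of new samples x p.
#' @param times Evaluation times.
#' @return Matrix samples x times of survival probabilities.
#' @export
predict_survival <- function(fit, bs, covariates, times) {
  lp <- drop(as.matrix(covariates) %*% fit$beta)
  outer(exp(lp), s0_at(bs, times), function(r, s) s^r)
}

#' Consensus rule for the cross-cohort prognostic screen
#'
#' A gene is selected when its univariate Cox association reaches
#' `p < p_threshold` in at least `min_cohorts` of the cohorts and (when
#' `require_direction`) the hazard ratios of those qualifying cohorts all
#' fall on the same side of 1.
#'
#' @param p_threshold Wald p-value threshold (default 0.05).
#' @param min_cohorts Minimum number of qualifying cohorts (default 8,
#'   interpreted as `>= 8`).
#' @param require_direction Require a consistent hazard direction across
#'   qualifying cohorts (default `TRUE`).
#' @return Object of class `consensus_rule`.
#' @export
consensus_rule <- function(p_threshold = 0.05, min_cohorts = 8,
                           require_direction = TRUE) {
  stopifnot(p_threshold > 0, p_threshold < 1, is_count(min_cohorts), min_cohorts >= 1)
  structure(list(p_threshold = p_threshold, min_cohorts = as.integer(min_cohorts),
                 require_direction = isTRUE(require_direction)),
            class = "consensus_rule")
}

#' Cross-cohort consensus prognostic-gene screen
#'
#' Fits one univariate Cox model per gene per cohort (gene expression as the
#' sole covariate) and applies the consensus rule. A per-cohort fit failure
#' or non-convergence marks that cohort non-qualifying for that gene and is
#' logged; the screen never aborts.
#'
#' @param mc A `multicohort` (cohort-standardized expression recommended;
#'   see [standardize()]).
#' @param rule A [consensus_rule()].
#' @param ties Tie handling passed to the Cox fits.
#' @return data.frame with one row per shared gene: per-cohort `hr_*` and
#'   `p_*` columns, `n_qualifying`, `direction_consistent`, `selected`.
#' @export
consensus_screen <- function(mc, rule = consensus_rule(),
                             ties = c("efron", "breslow")) {
  stopifnot(inherits(mc, "multicohort"), inherits(rule, "consensus_rule"))
  ties <- match.arg(ties)
  K <- length(mc$cohorts)
  if (rule$min_cohorts > K)
    cs_stop("min_cohorts (%d) exceeds cohort count (%d)", rule$min_cohorts, K)
  genes <- mc$shared_genes
  G <- length(genes)
  hr <- p <- matrix(NA_real_, G, K, dimnames = list(genes, names(mc$cohorts)))
  n_fail <- 0L
  for (k in seq_len(K)) {
    co <- mc$cohorts[[k]]
    st <- cox_structure(co$surv$time, co$surv$event)
    Xall <- t(co$expr)[st$ord, , drop = FALSE]
    for (g in seq_len(G)) {
      res <- tryCatch(cox_newton(Xall[, g, drop = FALSE], st, ties = ties),
                      error = function(e) NULL)
      if (is.null(res) || !res$converged || !is.finite(res$se[1]) || res$se[1] == 0) {
        n_fail <- n_fail + 1L
        next
      }
      hr[g, k] <- exp(res$beta[1])
      p[g, k] <- stats::pchisq((res$beta[1] / res$se[1])^2, 1, lower.tail = FALSE)
    }
  }
  if (n_fail > 0)
    cs_log("INFO", "consensus_screen",
           sprintf("%d per-cohort fits failed and were marked non-qualifying", n_fail))
  qual <- !is.na(p) & p < rule$p_threshold
  n_qualifying <- rowSums(qual)
  direction_consistent <- vapply(seq_len(G), function(g) {
    h <- hr[g, qual[g, ]]
    length(h) == 0L || all(h > 1) || all(h < 1)
  }, logical(1))
  selected <- n_qualifying >= rule$min_cohorts &
    (!rule$require_direction | direction_consistent)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    out[[paste0("hr_", names(mc$cohorts)[k])]] <- hr[, k]
    out[[paste0("p_", names(mc$cohorts)[k])]] <- p[, k]
  }
  out$n_qualifying <- as.integer(n_qualifying)
  out$direction_consistent <- direction_consistent
  out$selected <- selected
  rownames(out) <- NULL
  attr(out, "rule") <- rule
  out
}

#' Write screen records to TSV
#'
#' @param records Output of [consensus_screen()].
#' @param path Output file.
#' @export
write_screen <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(records)
}
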