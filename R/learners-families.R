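# Family internals behind fit_learner(). Each fit_* returns a list with
# `params` (whatever the family needs to score new samples), `orientation`,
# `selected_genes` (selectors; ordered), and `cv_record`.
#
# Penalized Cox goes through glmnet, survival forests through ranger,
# gradient boosting through xgboost; componentwise likelihood boosting,
# the linear ranking survival SVM, supervised principal components, and
# PLS-Cox are implemented here.

## ---- penalized Cox (LASSO / Ridge / Enet) ----------------------------------

fit_penalized <- function(spec, X, surv, fold_id, alpha) {
  y <- survival::Surv(surv$time, surv$event)
  pad <- ncol(X) < 2
  Xg <- if (pad) cbind(X, `..pad` = 0) else X
  lam <- spec$hyper_grid$lambda
  full <- if (is.null(lam))
    glmnet::glmnet(Xg, y, family = "cox", alpha = alpha, nlambda = 100,
                   standardize = FALSE, thresh = 1e-10)
  else
    glmnet::glmnet(Xg, y, family = "cox", alpha = alpha, lambda = lam,
                   standardize = FALSE, thresh = 1e-12)
  lam <- full$lambda
  if (length(lam) > 1) {
    # lambda path is decreasing = increasing complexity; ties pick largest
    tune <- cv_tune(Xg, surv, fold_id, as.list(lam),
      fit_fun = function(Xtr, str)
        glmnet::glmnet(Xtr, survival::Surv(str$time, str$event), family = "cox",
                       alpha = alpha, lambda = lam, standardize = FALSE,
                       thresh = 1e-10),
      score_fun = function(model, Xte, l)
        drop(stats::predict(model, newx = Xte, s = l, type = "link")))
    best_lam <- lam[tune$best]
    cvc <- tune$mean_c[tune$best]
  } else {
    best_lam <- lam
    cvc <- NA_real_
  }
  beta <- drop(as.matrix(stats::coef(full, s = best_lam)))
  if (pad) beta <- beta[colnames(X)]
  list(params = list(beta = beta),
       orientation = "higher_is_risk",
       selected_genes = if (spec$family %in% c("LASSO", "Enet"))
         order_selected(beta) else character(0),
       cv_record = list(lambda = best_lam, alpha = alpha, cv_cindex = cvc))
}

## ---- componentwise likelihood boosting (CoxBoost analogue) ------------------

## One boosting path: at each step every coordinate's penalized one-step
## Newton update is evaluated from the Breslow score U_j and curvature
## I_jj, and only the coordinate with the largest penalized score statistic
## U_j^2/(I_jj + penalty) is updated by U_j/(I_jj + penalty).
coxboost_path <- function(Xs, st, penalty, m_max) {
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- numeric(p)
  eta <- numeric(n)
  path <- matrix(0, m_max + 1L, p, dimnames = list(NULL, colnames(Xs)))
  eg <- st$event_groups
  fe <- st$first[eg]
  d <- st$d[eg]
  delta <- st$event
  for (m in seq_len(m_max)) {
    w <- exp(eta - max(eta))
    rc_w <- revcumsum(w)
    S0 <- rc_w[fe]
    # cumulative baseline hazard at each sample's own time
    Lam <- c(0, cumsum(d / S0))[findInterval(st$time, st$ut[eg]) + 1L]
    mres <- delta - w * Lam
    U <- drop(crossprod(Xs, mres))
    wX <- Xs * w
    S1 <- revcumsum(wX)[fe, , drop = FALSE]
    S2 <- revcumsum(wX * Xs)[fe, , drop = FALSE]
    m1 <- S1 / S0
    I <- colSums(d * (S2 / S0 - m1^2))
    stat <- U^2 / (I + penalty)
    j <- which.max(stat)
    upd <- U[j] / (I[j] + penalty)
    beta[j] <- beta[j] + upd
    eta <- eta + Xs[, j] * upd
    path[m + 1L, ] <- beta
  }
  path
}

fit_coxboost <- function(spec, X, surv, fold_id) {
  grid <- spec$hyper_grid$M %||% seq(0L, 100L, by = 5L)
  grid <- sort(unique(as.integer(grid)))
  penalty <- spec$hyper_grid$penalty %||% (9 * sum(surv$event))
  m_max <- max(grid)
  if (length(grid) > 1) {
    tune <- cv_tune(X, surv, fold_id, as.list(grid),
      fit_fun = function(Xtr, str) {
        st <- cox_structure(str$time, str$event)
        coxboost_path(Xtr[st$ord, , drop = FALSE], st, penalty, m_max)
      },
      score_fun = function(path, Xte, M) drop(Xte %*% path[M + 1L, ]))
    best_M <- grid[tune$best]
    cvc <- tune$mean_c[tune$best]
  } else {
    best_M <- grid
    cvc <- NA_real_
  }
  st <- cox_structure(surv$time, surv$event)
  path <- coxboost_path(X[st$ord, , drop = FALSE], st, penalty, best_M)
  beta <- path[best_M + 1L, ]
  list(params = list(beta = beta),
       orientation = "higher_is_risk",
       selected_genes = order_selected(beta),
       cv_record = list(M = best_M, penalty = penalty, cv_cindex = cvc))
}

## ---- stepwise Cox -----------------------------------------------------------

## gene ids may not be syntactic R names; map and restore
safe_names <- function(genes) {
  nm <- make.names(genes, unique = TRUE)
  stats::setNames(genes, nm)
}

fit_stepcox <- function(spec, X, surv) {
  map <- safe_names(colnames(X))
  df <- data.frame(time = surv$time, event = surv$event, X)
  names(df)[-(1:2)] <- names(map)
  full_f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                    paste(names(map), collapse = " + ")))
  null_f <- stats::as.formula("survival::Surv(time, event) ~ 1")
  start <- if (spec$direction == "forward")
    survival::coxph(null_f, data = df)
  else
    suppressWarnings(survival::coxph(full_f, data = df))
  sel <- suppressWarnings(
    stats::step(start, scope = list(lower = null_f, upper = full_f),
                direction = spec$direction, trace = 0, k = 2))
  cf <- stats::coef(sel)
  beta <- stats::setNames(numeric(length(map)), unname(map))
  if (length(cf)) beta[map[names(cf)]] <- cf
  list(params = list(beta = beta, aic = stats::extractAIC(sel)[2]),
       orientation = "higher_is_risk",
       selected_genes = order_selected(beta),
       cv_record = list(direction = spec$direction))
}

## ---- random survival forest (ranger) ---------------------------------------

fit_rsf <- function(spec, X, surv, cv) {
  map <- safe_names(colnames(X))
  df <- data.frame(time = surv$time, event = surv$event, X)
  names(df)[-(1:2)] <- names(map)
  num_trees <- spec$hyper_grid$num_trees %||% 500
  seed <- derive_seed(cv$seed, paste0("rsf:", spec$label))
  rf <- ranger::ranger(
    stats::as.formula("survival::Surv(time, event) ~ ."),
    data = df, num.trees = num_trees, splitrule = "logrank",
    importance = "permutation", seed = seed, num.threads = 1)
  imp <- ranger::importance(rf)
  names(imp) <- unname(map[names(imp)])
  # permutation importances of null genes scatter symmetrically around zero,
  # so the magnitude of the most negative one estimates the noise scale;
  # genes must clear it to be selected
  thr <- max(0, -min(imp))
  list(params = list(rf = rf, map = map, importance = imp),
       orientation = "higher_is_risk",
       selected_genes = order_selected(imp[imp > thr]),
       cv_record = list(num_trees = num_trees, seed = seed,
                        importance_threshold = thr))
}

## ---- gradient boosting of the Cox partial likelihood (xgboost) -------------

fit_gbm <- function(spec, X, surv, fold_id, cv) {
  grid <- spec$hyper_grid$nrounds %||% c(10L, 25L, 50L, 100L)
  grid <- sort(unique(as.integer(grid)))
  seed <- derive_seed(cv$seed, paste0("gbm:", spec$label))
  params <- list(objective = "survival:cox", eta = 0.1, max_depth = 2,
                 subsample = 0.8, nthread = 1, seed = seed)
  ylab <- function(s) ifelse(s$event == 1, s$time, -s$time)
  m_max <- max(grid)
  if (length(grid) > 1) {
    tune <- cv_tune(X, surv, fold_id, as.list(grid),
      fit_fun = function(Xtr, str) {
        dtr <- xgboost::xgb.DMatrix(Xtr, label = ylab(str))
        xgboost::xgb.train(params, dtr, nrounds = m_max, verbose = 0)
      },
      score_fun = function(model, Xte, M)
        stats::predict(model, xgboost::xgb.DMatrix(Xte), outputmargin = TRUE,
                       iterationrange = c(1, M + 1)))
    best_M <- grid[tune$best]
    cvc <- tune$mean_c[tune$best]
  } else {
    best_M <- grid
    cvc <- NA_real_
  }
  dall <- xgboost::xgb.DMatrix(X, label = ylab(surv))
  booster <- xgboost::xgb.train(params, dall, nrounds = best_M, verbose = 0)
  list(params = list(booster = booster),
       orientation = "higher_is_risk",
       selected_genes = character(0),
       cv_record = list(nrounds = best_M, cv_cindex = cvc))
}

## ---- linear ranking survival SVM -------------------------------------------

## Squared-hinge ranking objective over comparable pairs (earlier event i,
## later j): 0.5 ||w||^2 + cost/|P| * sum max(0, 1 - (s_j - s_i))^2 with
## s = Xw, so higher scores predict longer survival.
fit_survsvm <- function(spec, X, surv) {
  cost <- spec$hyper_grid$cost %||% 1.0
  max_pairs <- spec$hyper_grid$max_pairs %||% 50000L
  n <- nrow(X)
  lt <- outer(surv$time, surv$time, "<")
  cmp <- which(lt & surv$event == 1, arr.ind = TRUE)   # row i earlier event
  if (nrow(cmp) == 0) cs_stop("SurvSVM: no comparable pairs")
  if (nrow(cmp) > max_pairs)
    cmp <- cmp[sample(nrow(cmp), max_pairs), , drop = FALSE]
  D <- X[cmp[, 2], , drop = FALSE] - X[cmp[, 1], , drop = FALSE]  # x_j - x_i
  np <- nrow(D)
  fn <- function(w) {
    h <- pmax(0, 1 - drop(D %*% w))
    0.5 * sum(w^2) + cost * sum(h^2) / np
  }
  gr <- function(w) {
    h <- pmax(0, 1 - drop(D %*% w))
    w - 2 * cost / np * drop(crossprod(D, h))
  }
  opt <- stats::optim(numeric(ncol(X)), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  w <- stats::setNames(opt$par, colnames(X))
  list(params = list(w = w, cost = cost),
       orientation = "higher_is_protective",
       selected_genes = character(0),
       cv_record = list(cost = cost, converged = opt$convergence == 0))
}

## ---- supervised principal components ---------------------------------------

## univariate Cox score-test z at beta = 0 for every column
cox_score_z <- function(X, st) {
  Xs <- X[st$ord, , drop = FALSE]
  eg <- st$event_groups
  fe <- st$first[eg]
  d <- st$d[eg]
  nrisk <- rev(seq_len(st$n))[fe]
  Lam <- c(0, cumsum(d / nrisk))[findInterval(st$time, st$ut[eg]) + 1L]
  m0 <- st$event - Lam
  U <- drop(crossprod(Xs, m0))
  S1 <- revcumsum(Xs)[fe, , drop = FALSE]
  S2 <- revcumsum(Xs^2)[fe, , drop = FALSE]
  m1 <- S1 / nrisk
  I <- colSums(d * (S2 / nrisk - m1^2))
  z <- U / sqrt(pmax(I, .Machine$double.eps))
  stats::setNames(z, colnames(X))
}

superpc_fit_one <- function(Xtr, str, genes, k) {
  if (length(genes) < k) return(NULL)
  sub <- Xtr[, genes, drop = FALSE]
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  comp <- pc$x[, seq_len(k), drop = FALSE]
  fit <- tryCatch(fit_cox(comp, str), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  list(genes = genes, center = pc$center,
       rotation = pc$rotation[, seq_len(k), drop = FALSE], beta = fit$beta)
}

superpc_score <- function(model, Xte) {
  sub <- sweep(Xte[, model$genes, drop = FALSE], 2, model$center)
  drop(sub %*% model$rotation %*% model$beta)
}

fit_superpc <- function(spec, X, surv, fold_id) {
  st <- cox_structure(surv$time, surv$event)
  z <- abs(cox_score_z(X, st))
  thr_probs <- spec$hyper_grid$threshold_quantiles %||% seq(0, 0.9, by = 0.1)
  thrs <- unique(stats::quantile(z, probs = thr_probs, names = FALSE))
  ks <- spec$hyper_grid$k %||% 1:3
  # grid ordered by complexity: fewest components, then fewest genes
  grid <- expand.grid(k = sort(ks), thr = sort(thrs, decreasing = TRUE))
  nf <- max(fold_id)
  cmat <- matrix(NA_real_, nf, nrow(grid))
  for (f in seq_len(nf)) {
    tr <- fold_id != f
    str <- surv[tr, , drop = FALSE]
    stf <- tryCatch(cox_structure(str$time, str$event), error = function(e) NULL)
    if (is.null(stf)) next
    zf <- abs(cox_score_z(X[tr, , drop = FALSE], stf))
    for (gi in seq_len(nrow(grid))) {
      genes <- names(zf)[zf >= grid$thr[gi]]
      model <- superpc_fit_one(X[tr, , drop = FALSE], str, genes, grid$k[gi])
      if (is.null(model)) next
      sc <- superpc_score(model, X[!tr, , drop = FALSE])
      cmat[f, gi] <- cindex_quick(sc, surv$time[!tr], surv$event[!tr])
    }
  }
  mean_c <- colMeans(cmat, na.rm = TRUE)
  mean_c[is.nan(mean_c)] <- -Inf
  if (all(!is.finite(mean_c))) cs_stop("SuperPC: no valid (threshold, k) configuration")
  best <- which(mean_c == max(mean_c))[1]
  genes <- names(z)[z >= grid$thr[best]]
  model <- superpc_fit_one(X, surv, genes, grid$k[best])
  if (is.null(model)) cs_stop("SuperPC: final fit failed")
  list(params = model,
       orientation = "higher_is_risk",
       selected_genes = character(0),
       cv_record = list(threshold = grid$thr[best], k = grid$k[best],
                        cv_cindex = mean_c[best]))
}

## ---- partial least squares Cox ---------------------------------------------

## Sequential PLS components for the Cox model: each weight vector is the
## covariance of the (deflated) expression with the current martingale
## residuals; X is deflated against each extracted component; a Cox model on
## the components supplies the next residuals.
plsrcox_build <- function(X, surv, ncomp) {
  st <- cox_structure(surv$time, surv$event)
  center <- colMeans(X)
  Xd <- sweep(X, 2, center)
  # null-model martingale residuals (Nelson-Aalen)
  eg <- st$event_groups; fe <- st$first[eg]
  nrisk <- rev(seq_len(st$n))[fe]
  Lam0 <- c(0, cumsum(st$d[eg] / nrisk))[findInterval(st$time, st$ut[eg]) + 1L]
  r <- numeric(st$n); r[st$ord] <- st$event - Lam0
  W <- P <- matrix(0, ncol(X), 0)
  Tm <- matrix(0, nrow(X), 0)
  betas <- vector("list", ncomp)
  for (c in seq_len(ncomp)) {
    wc <- drop(crossprod(Xd, r))
    nw <- sqrt(sum(wc^2))
    if (nw < 1e-12) break
    wc <- wc / nw
    tc <- drop(Xd %*% wc)
    pc <- drop(crossprod(Xd, tc)) / sum(tc^2)
    Xd <- Xd - tcrossprod(tc, pc)
    W <- cbind(W, wc); P <- cbind(P, pc); Tm <- cbind(Tm, tc)
    colnames(Tm) <- paste0("comp", seq_len(ncol(Tm)))
    fit <- tryCatch(fit_cox(Tm, surv), error = function(e) NULL)
    if (is.null(fit)) break
    betas[[c]] <- unname(fit$beta)
    # residuals from the current fit (Breslow baseline)
    eta <- drop(Tm %*% fit$beta)
    w <- exp(eta[st$ord] - max(eta))
    rc_w <- revcumsum(w)
    S0 <- rc_w[fe]
    Lam <- c(0, cumsum(st$d[eg] / S0))[findInterval(st$time, st$ut[eg]) + 1L]
    r[st$ord] <- st$event - w * Lam
  }
  ncomp_built <- ncol(W)
  list(center = center, W = W, P = P,
       betas = betas[seq_len(ncomp_built)], ncomp = ncomp_built)
}

plsrcox_components <- function(model, Xte, ncomp) {
  Xd <- sweep(Xte, 2, model$center)
  Tm <- matrix(0, nrow(Xte), ncomp)
  for (c in seq_len(ncomp)) {
    Tm[, c] <- drop(Xd %*% model$W[, c])
    Xd <- Xd - tcrossprod(Tm[, c], model$P[, c])
  }
  Tm
}

fit_plsrcox <- function(spec, X, surv, fold_id) {
  ncomp_grid <- spec$hyper_grid$ncomp %||% seq_len(min(5L, ncol(X)))
  ncomp_grid <- sort(unique(as.integer(ncomp_grid)))
  m_max <- max(ncomp_grid)
  tune <- cv_tune(X, surv, fold_id, as.list(ncomp_grid),
    fit_fun = function(Xtr, str) plsrcox_build(Xtr, str, m_max),
    score_fun = function(model, Xte, nc) {
      nc <- min(nc, model$ncomp)
      if (nc < 1 || is.null(model$betas[[nc]])) stop("no components")
      drop(plsrcox_components(model, Xte, nc) %*% model$betas[[nc]])
    })
  best_nc <- ncomp_grid[tune$best]
  model <- plsrcox_build(X, surv, best_nc)
  best_nc <- min(best_nc, model$ncomp)
  list(params = c(model, list(use_ncomp = best_nc)),
       orientation = "higher_is_risk",
       selected_genes = character(0),
       cv_record = list(ncomp = best_nc, cv_cindex = tune$mean_c[tune$best]))
}

## ---- scoring dispatch -------------------------------------------------------

predict_family <- function(fl, X) {
  p <- fl$params
  switch(fl$spec$family,
    LASSO = , Ridge = , Enet = , CoxBoost = , StepCox =
      drop(X %*% p$beta[colnames(X)]),
    SurvSVM = drop(X %*% p$w[colnames(X)]),
    SuperPC = superpc_score(p, X),
    plsRcox = drop(plsrcox_components(p, X, p$use_ncomp) %*% p$betas[[p$use_ncomp]]),
    RSF = {
      df <- as.data.frame(X)
      names(df) <- names(p$map)[match(colnames(X), p$map)]
      pr <- stats::predict(p$rf, data = df, num.threads = 1)
      chf <- pr$chf
      chf[, ncol(chf)]
    },
    GBM = stats::predict(p$booster, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
  )
}
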