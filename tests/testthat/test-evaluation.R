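# Concordance, C-index comparison, IPCW AUC, KM/log-rank, calibration,
# external signatures.

library(survival)

test_that("C-index matches hand enumeration and the brute-force oracle", {
  surv <- data.frame(time = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
  expect_equal(harrell_cindex(c(5, 4, 3, 6), surv)$cindex, 0.6)
  # perfect risk ordering of uncensored times
  surv2 <- data.frame(time = c(5, 3, 9, 1), event = rep(1, 4))
  expect_equal(harrell_cindex(-surv2$time, surv2)$cindex, 1.0)
  # random instances against the O(n^2) pair-enumeration oracle
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    time <- sample(1:15, n, replace = TRUE) + runif(n) * (i %% 2)  # some ties
    event <- rbinom(n, 1, 0.7)
    scores <- sample(1:8, n, replace = TRUE)
    if (sum(event) == 0) next
    oracle <- cindex_oracle(scores, time, event)
    if (is.na(oracle)) next
    expect_identical(harrell_cindex(scores, data.frame(time = time, event = event))$cindex,
                     oracle)
  }
  expect_error(harrell_cindex(1:3, data.frame(time = 1:3, event = c(0, 0, 0))),
               "event|usable")
})

test_that("negating tie-free scores reflects the C-index around 1/2", {
  set.seed(103)
  n <- 60
  surv <- data.frame(time = runif(n), event = rbinom(n, 1, 0.6))
  sc <- rnorm(n)
  c1 <- harrell_cindex(sc, surv)$cindex
  c2 <- harrell_cindex(-sc, surv)$cindex
  expect_equal(c1, 1 - c2)
})

test_that("compare_cindex: identity gives p 1, informative vs permuted rejects", {
  set.seed(107)
  co <- sim_single_cohort(n = 300, G = 3, planted = c(g0001 = 1.0), seed = 107)
  truth <- co$expr["g0001", ]
  res0 <- compare_cindex(truth, truth, co$surv)
  expect_equal(res0$delta, 0)
  expect_equal(res0$p, 1)
  perm <- sample(truth)
  res1 <- compare_cindex(truth, perm, co$surv)
  expect_lt(res1$p, 0.01)
  expect_gt(res1$delta, 0)
  # jackknife variance agrees with bootstrap within a factor of 1.5
  set.seed(109)
  co2 <- sim_single_cohort(n = 100, G = 3, planted = c(g0001 = 0.8), seed = 109)
  sA <- co2$expr["g0001", ] + rnorm(100, sd = 0.5)
  sB <- co2$expr["g0001", ] + rnorm(100, sd = 1.5)
  jk <- compare_cindex(sA, sB, co2$surv)
  jk_se <- abs(jk$delta / jk$z)
  boot <- replicate(2000, {
    idx <- sample(100, replace = TRUE)
    srv <- co2$surv[idx, ]
    tryCatch(harrell_cindex(sA[idx], srv)$cindex - harrell_cindex(sB[idx], srv)$cindex,
             error = function(e) NA)
  })
  ratio <- jk_se / sd(boot, na.rm = TRUE)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("IPCW AUC: uncensored limit, monotone invariance, permutation null", {
  set.seed(113)
  n <- 300
  time <- rexp(n); event <- rep(1L, n); sc <- rnorm(n) - time
  surv <- data.frame(time = time, event = event)
  t0 <- quantile(time, 0.5)
  lab <- time <= t0
  plain <- mean(outer(sc[lab], sc[!lab], ">") + 0.5 * outer(sc[lab], sc[!lab], "=="))
  expect_lt(abs(time_auc(sc, surv, t0)$auc - plain), 1e-12)
  # strictly monotone transforms leave the estimate unchanged
  surv2 <- data.frame(time = time, event = rbinom(n, 1, 0.7))
  pos <- abs(sc) + 1
  a1 <- time_auc(pos, surv2, t0)$auc
  expect_lt(abs(time_auc(exp(pos), surv2, t0)$auc - a1), 1e-12)
  expect_lt(abs(time_auc(log(pos), surv2, t0)$auc - a1), 1e-12)
  # true linear predictor on strong signal scores high; permuted is near 1/2
  co <- sim_single_cohort(n = 1000, G = 2, planted = c(g0001 = 2.0), seed = 113,
                          censor_target = 0.2)
  truth <- co$expr["g0001", ]
  hz <- quantile(co$surv$time, c(0.3, 0.6))
  expect_true(all(time_auc(truth, co$surv, hz)$auc > 0.8))
  perm <- sample(truth)
  expect_true(all(abs(time_auc(perm, co$surv, hz)$auc - 0.5) < 0.05))
  expect_error(time_auc(truth, co$surv, max(co$surv$time) + 1), "horizon")
})

test_that("log-rank: identical groups give chi-square 0; matches survdiff", {
  co <- toy_cohort(n = 20, g = 2, seed = 127)
  both <- rbind(co$surv, co$surv)
  res <- km_logrank(rep(c("a", "b"), each = 20), both)
  expect_lt(res$chisq, 1e-10)
  expect_equal(res$p, 1)
  # hand-computed single-event case: one event at t=1 in A, B censored later
  surv <- data.frame(time = c(1, 2), event = c(1, 0))
  res1 <- km_logrank(c("A", "B"), surv)
  # 2x2 table at t=1: 1 death among 2 at risk, 1 per group: O-E = 1 - 0.5
  expect_equal(res1$chisq, (0.5)^2 / 0.25)
  # random instances against survival::survdiff
  set.seed(131)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    time <- sample(1:12, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    grp <- sample(letters[1:sample(2:3, 1)], n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    mine <- km_logrank(grp, data.frame(time = time, event = event))
    ref <- survdiff(Surv(time, event) ~ grp)
    expect_lt(abs(mine$chisq - ref$chisq), 1e-10)
  }
})

test_that("KM curves equal the empirical survival function without censoring", {
  tx <- c(3, 1, 4, 3, 1)
  surv <- data.frame(time = c(tx, 1, 5), event = 1L)
  res <- km_logrank(c(rep("x", 5), "y", "y"), surv)
  cx <- res$curves[res$curves$group == "x", ]
  emp <- sapply(cx$time, function(t) mean(tx > t))
  expect_equal(cx$surv, emp)
})

test_that("calibration: model-faithful predictions are close, degenerate cases flagged", {
  # Weibull PH simulation scored with its own true survival function
  cfg <- sim_config(K = 1, n_per_cohort = 1000, G = 5, planted = c(g0001 = 0.7),
                    batch_shift_sd = 0, batch_scale_range = c(1, 1),
                    censor_target = 0.3, seed = 137)
  sim <- simulate_multicohort(cfg)
  co <- sim$multicohort$cohorts[[1]]
  lp <- sim$truth$lp[[1]][co$surv$sample_id]
  t0 <- quantile(co$surv$time, 0.4)
  true_prob <- exp(-(t0 / 24)^1.2 * exp(lp))
  cal <- calibration_curve(true_prob, co$surv, t0, n_bins = 4)
  expect_lte(mean(abs(cal$mean_predicted - cal$observed)), 0.05)
  # anti-calibrated predictions deviate badly and cross
  anti <- calibration_curve(1 - true_prob, co$surv, t0, n_bins = 4)
  expect_gt(mean(abs(anti$mean_predicted - anti$observed)), 0.2)
  # constant predictions collapse to one bin equal to the overall KM
  expect_warning(flat <- calibration_curve(rep(0.5, nrow(co$surv)), co$surv, t0),
                 "constant")
  expect_equal(nrow(flat), 1L)
  km <- summary(survfit(Surv(co$surv$time, co$surv$event) ~ 1), times = t0)$surv
  expect_equal(flat$observed, km)
})

test_that("external signatures apply as dot products with coverage accounting", {
  co <- toy_cohort(n = 2, g = 4, seed = 139, censor = 0)
  sig <- external_signature("pub1", c(gene1 = 0.5, gene2 = -1, gene3 = 2))
  sc <- apply_signature(sig, co)
  manual <- 0.5 * co$expr["gene1", ] - 1 * co$expr["gene2", ] + 2 * co$expr["gene3", ]
  expect_equal(unname(sc), unname(manual), ignore_attr = TRUE)
  # one absent gene with drop policy
  sig2 <- external_signature("pub2", c(gene1 = 1, gene2 = 1, nope = 1))
  sc2 <- apply_signature(sig2, co)
  expect_equal(attr(sc2, "coverage")$fraction, 2 / 3)
  expect_identical(attr(sc2, "coverage")$missing, "nope")
  expect_error(apply_signature(sig2, co, missing_policy = "error"), "nope")
  sig3 <- external_signature("pub3", c(zz = 1))
  expect_error(apply_signature(sig3, co), "no signature genes")
})

test_that("evaluate_scores assembles a coherent report", {
  co <- sim_single_cohort(n = 250, G = 5, planted = c(g0001 = 0.9), seed = 149)
  co$surv$age <- rnorm(250, 60, 8)
  sc <- co$expr["g0001", ]
  rep <- suppressWarnings(
    evaluate_scores(sc, co, horizons = quantile(co$surv$time, c(0.3, 0.5)),
                    covariates = "age"))
  expect_gt(rep$cindex$cindex, 0.6)
  expect_true(all(rep$auc$auc > 0.5, na.rm = TRUE))
  expect_lt(rep$logrank$p, 0.05)
  expect_identical(names(rep$adjusted$beta)[1], "score")
})
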