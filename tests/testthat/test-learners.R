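# The ten learner families behind the uniform fit/score/select contract.

test_that("penalized Cox: huge lambda empties the model, lambda 0 matches Newton", {
  co <- sim_single_cohort(n = 200, G = 3,
                          planted = c(g0001 = 0.6, g0002 = -0.4), seed = 41)
  cv <- cv_plan(10, seed = 2)
  big <- fit_learner(algorithm_spec("LASSO", hyper_grid = list(lambda = 50)), co, cv)
  expect_true(all(big$params$beta == 0))
  expect_length(big$selected_genes, 0)
  expect_error(select_features(big), "no genes")

  zero <- fit_learner(algorithm_spec("LASSO", hyper_grid = list(lambda = 0)), co, cv)
  mle <- fit_cox(t(co$expr), co$surv, ties = "breslow")
  expect_lt(max(abs(zero$params$beta - mle$beta)), 1e-4)
})

test_that("lasso path is monotone in support size and cv folds partition samples", {
  co <- sim_single_cohort(n = 150, G = 25, planted = c(g0001 = 0.8), seed = 43)
  y <- survival::Surv(co$surv$time, co$surv$event)
  path <- glmnet::glmnet(t(co$expr), y, family = "cox", standardize = FALSE)
  nnz <- colSums(as.matrix(path$beta) != 0)
  # support grows (weakly) as lambda decreases along the path
  expect_true(all(diff(nnz[order(path$lambda, decreasing = TRUE)]) >= -1e-9))
  folds <- consurv:::make_folds(150, sum(co$surv$event), cv_plan(10, 1))
  expect_length(folds, 150)
  expect_setequal(unique(folds), 1:10)
})

test_that("componentwise boosting: step counts, and the MLE limit at zero penalty", {
  co <- sim_single_cohort(n = 150, G = 2,
                          planted = c(g0001 = 0.5, g0002 = -0.5), seed = 47)
  cv <- cv_plan(10, seed = 5)
  m0 <- fit_learner(algorithm_spec("CoxBoost", hyper_grid = list(M = 0)), co, cv)
  expect_true(all(m0$params$beta == 0))
  m1 <- fit_learner(algorithm_spec("CoxBoost", hyper_grid = list(M = 1)), co, cv)
  expect_equal(sum(m1$params$beta != 0), 1L)
  mfull <- fit_learner(
    algorithm_spec("CoxBoost", hyper_grid = list(M = 2000, penalty = 0)), co, cv)
  mle <- fit_cox(t(co$expr), co$surv, ties = "breslow")
  expect_lt(max(abs(mfull$params$beta - mle$beta)), 1e-2)
})

test_that("stepwise Cox recovers the single informative gene and beats the null AIC", {
  co <- sim_single_cohort(n = 300, G = 8, planted = c(g0001 = 1.0), seed = 53)
  fl <- fit_learner(algorithm_spec("StepCox", direction = "both"), co, cv_plan(10, 1))
  expect_true("g0001" %in% fl$selected_genes)
  null_aic <- stats::extractAIC(
    survival::coxph(survival::Surv(time, event) ~ 1,
                    data = co$surv))[2]
  expect_lt(fl$params$aic, null_aic)
})

test_that("survival SVM reaches concordance 1 on a perfectly ordering gene", {
  n <- 100
  set.seed(61)
  expr <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("gene1", "gene2"), paste0("s", 1:n)))
  expr[2, ] <- 5                      # constant decoy; zero after standardizing
  # survival time strictly increasing in gene1, no censoring
  surv <- data.frame(sample_id = colnames(expr),
                     time = rank(expr[1, ]) + 0.5, event = 1L)
  co <- standardize(cohort("svmtoy", expr, surv))
  fl <- fit_learner(algorithm_spec("SurvSVM"), co, cv_plan(10, 1))
  expect_identical(fl$orientation, "higher_is_protective")
  sc <- predict_scores(fl, co)
  expect_equal(harrell_cindex(consurv:::as_risk(sc), co$surv)$cindex, 1.0)
})

test_that("RSF selection: sparse on pure noise, recovers planted genes on signal", {
  co <- sim_single_cohort(n = 150, G = 50, planted = numeric(0), seed = 3)
  fl <- fit_learner(algorithm_spec("RSF"), co, cv_plan(10, 3))
  expect_lt(length(fl$selected_genes) / 50, 0.2)
  sig <- sim_single_cohort(n = 200, G = 20,
                           planted = c(g0001 = 0.9, g0002 = -0.9), seed = 4)
  fl2 <- fit_learner(algorithm_spec("RSF"), sig, cv_plan(10, 4))
  expect_true(all(c("g0001", "g0002") %in% fl2$selected_genes))
})

test_that("every family scores with the declared orientation better than chance", {
  planted <- c(g0001 = 0.7, g0002 = -0.7, g0003 = 0.5)
  train <- sim_single_cohort(n = 500, G = 12, planted = planted, seed = 67)
  cv <- cv_plan(10, seed = 7)
  specs <- list(
    algorithm_spec("LASSO"), algorithm_spec("Ridge"),
    algorithm_spec("Enet", alpha = 0.5), algorithm_spec("GBM"),
    algorithm_spec("SurvSVM"), algorithm_spec("SuperPC"),
    algorithm_spec("plsRcox"), algorithm_spec("CoxBoost"),
    algorithm_spec("StepCox", direction = "backward"), algorithm_spec("RSF"))
  for (spec in specs) {
    fl <- fit_learner(spec, train, cv)
    sc <- predict_scores(fl, train)
    C <- harrell_cindex(consurv:::as_risk(sc), train$surv)$cindex
    expect_gt(C, 0.5, label = paste(spec$label, "oriented C-index"))
  }
})

test_that("fits are deterministic under a fixed cv seed", {
  train <- sim_single_cohort(n = 120, G = 10, planted = c(g0001 = 0.8), seed = 71)
  cv <- cv_plan(5, seed = 13)
  for (fam in c("LASSO", "CoxBoost", "RSF", "GBM", "SurvSVM", "plsRcox")) {
    a <- fit_learner(algorithm_spec(fam), train, cv)
    b <- fit_learner(algorithm_spec(fam), train, cv)
    expect_identical(predict_scores(a, train), predict_scores(b, train),
                     label = paste(fam, "determinism"))
  }
})

test_that("linear scores equal the dot product and missing genes error", {
  co <- sim_single_cohort(n = 100, G = 3, planted = c(g0001 = 0.6), seed = 73)
  fl <- fit_learner(algorithm_spec("Ridge"), co, cv_plan(10, 1))
  sc <- predict_scores(fl, co)
  manual <- drop(crossprod(co$expr, fl$params$beta[rownames(co$expr)]))
  expect_equal(unname(as.numeric(sc)), unname(manual))
  # training sample duplicated -> identical score
  dup <- co$expr[, c(1, 1)]
  colnames(dup) <- c("a", "b")
  sdup <- predict_scores(fl, dup)
  expect_equal(unname(sdup[1]), unname(sdup[2]))
  expect_error(predict_scores(fl, co$expr[-1, , drop = FALSE]), "g0001")
})

test_that("select_features orders by magnitude with lexicographic ties", {
  fl <- structure(list(
    spec = algorithm_spec("LASSO"),
    genes_used = c("a", "b", "c", "d"),
    selected_genes = consurv:::order_selected(
      c(b = -0.5, a = 0.2, d = 0.5, c = 0)),
    orientation = "higher_is_risk", params = list()),
    class = "fitted_learner")
  expect_identical(select_features(fl), c("b", "d", "a"))
  gbm <- structure(list(spec = algorithm_spec("GBM"), selected_genes = character(0)),
                   class = "fitted_learner")
  expect_error(select_features(gbm), "not a selector")
})
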