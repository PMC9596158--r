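# Combination enumeration, the sweep engine, leaderboard ranking,
# stratification.

test_that("shipped rosters expand to the documented combination counts", {
  d <- enumerate_combinations(consurv:::roster_path("default"))
  expect_length(d, 76)
  labels <- vapply(d, `[[`, "", "label")
  expect_false(anyDuplicated(labels) > 0)
  expect_true("CoxBoost + SurvSVM" %in% labels)
  r <- enumerate_combinations(consurv:::roster_path("remodel"))
  expect_length(r, 18)
  expect_true(all(vapply(r, function(x) is.null(x$selector), TRUE)))
})

test_that("a one-selector one-modeler roster yields a single pair", {
  roster <- list(version = 1, pairing = "pairs",
                 selectors = list(list(family = "LASSO")),
                 modelers = list(list(family = "Ridge")))
  combos <- enumerate_combinations(roster)
  expect_length(combos, 1)
  expect_identical(combos[[1]]$label, "LASSO + Ridge")
  bad <- list(version = 1, pairing = "pairs",
              selectors = list(list(family = "Ridge")),
              modelers = list(list(family = "LASSO")))
  expect_error(enumerate_combinations(bad), "selector")
  expect_error(enumerate_combinations(list(pairing = "pairs")), "version")
  expect_error(
    enumerate_combinations(list(version = 1, pairing = "pairs",
                                selectors = list(list(family = "Frobnicator")),
                                modelers = list(list(family = "Ridge")))),
    "")
})

make_sweep_fixture <- function(seed = 11, K = 4, n = 120, G = 40) {
  planted <- stats::setNames(rep(c(0.6, -0.6), 5), sprintf("g%04d", 1:10))
  sim <- simulate_multicohort(sim_config(
    K = K, n_per_cohort = n, G = G, planted = planted, censor_target = 0.3,
    batch_shift_sd = 0.3, seed = seed))
  mc <- sim$multicohort
  mc$cohorts <- lapply(mc$cohorts, standardize)
  roles <- vapply(mc$cohorts, `[[`, "", "role")
  list(sim = sim,
       train = mc$cohorts[[which(roles == "training")]],
       testing = structure(list(cohorts = mc$cohorts[roles == "testing"],
                                shared_genes = mc$shared_genes),
                           class = "multicohort"))
}

test_that("run_combination fits, scores all cohorts, and skips on empty selection", {
  fx <- make_sweep_fixture()
  cv <- cv_plan(5, seed = 11)
  cspec <- enumerate_combinations(list(
    version = 1, pairing = "pairs",
    selectors = list(list(family = "LASSO")),
    modelers = list(list(family = "Ridge"))))[[1]]
  res <- suppressMessages(run_combination(cspec, fx$train, fx$testing, cv,
                                          rownames(fx$train$expr)))
  expect_identical(res$row$status, "ok")
  expect_gt(res$row$mean_testing_cindex, 0.6)
  # mean is over testing cohorts only
  cvals <- unlist(res$row[paste0("c_", names(fx$testing$cohorts))])
  expect_equal(unname(res$row$mean_testing_cindex), mean(cvals))
  expect_s3_class(res$signature, "signature_model")

  # selector forced to select nothing -> skipped, not an error
  empty_sel <- enumerate_combinations(list(
    version = 1, pairing = "pairs",
    selectors = list(list(family = "LASSO", hyper_grid = list(lambda = 99))),
    modelers = list(list(family = "Ridge"))))[[1]]
  res2 <- suppressWarnings(suppressMessages(
    run_combination(empty_sel, fx$train, fx$testing, cv,
                    rownames(fx$train$expr))))
  expect_identical(res2$row$status, "skipped")
  expect_match(res2$row$reason, "no genes")
})

test_that("testing cohorts never leak into fitting (poisoning them changes nothing)", {
  fx <- make_sweep_fixture(seed = 23)
  cv <- cv_plan(5, seed = 23)
  cspec <- enumerate_combinations(list(
    version = 1, pairing = "pairs",
    selectors = list(list(family = "CoxBoost")),
    modelers = list(list(family = "LASSO"))))[[1]]
  genes <- rownames(fx$train$expr)
  res1 <- suppressMessages(run_combination(cspec, fx$train, fx$testing, cv, genes))
  poisoned <- fx$testing
  poisoned$cohorts <- lapply(poisoned$cohorts, function(co) {
    co$surv$time <- rev(co$surv$time); co$surv$event <- rev(co$surv$event); co
  })
  res2 <- suppressMessages(run_combination(cspec, fx$train, poisoned, cv, genes))
  expect_identical(res1$signature$learner$params$beta,
                   res2$signature$learner$params$beta)
  expect_identical(res1$signature$genes, res2$signature$genes)
})

test_that("leaderboard ranks by mean testing C with documented tie-breaks", {
  rows <- data.frame(
    label = c("b", "a", "c", "d", "e"),
    status = c("ok", "ok", "ok", "ok", "skipped"),
    reason = c("", "", "", "", "boom"),
    n_selected_genes = c(9L, 5L, 5L, 3L, NA),
    mean_testing_cindex = c(0.70, 0.70, 0.70, 0.66, NA))
  lb <- build_leaderboard(rows)
  expect_identical(lb$label[1:4], c("a", "c", "b", "d"))
  expect_identical(attr(lb, "winner"), "a")
  expect_error(build_leaderboard(rows[rows$status == "skipped", ]), "skipped")
})

test_that("a small sweep is deterministic and its winner attains the max", {
  fx <- make_sweep_fixture(seed = 29)
  roster <- list(version = 1, pairing = "pairs",
                 selectors = list(list(family = "LASSO"), list(family = "CoxBoost")),
                 modelers = list(list(family = "Ridge"), list(family = "SurvSVM"),
                                 list(family = "plsRcox")))
  combos <- enumerate_combinations(roster)
  expect_length(combos, 6)
  cv <- cv_plan(5, seed = 29)
  genes <- rownames(fx$train$expr)
  sw1 <- suppressWarnings(suppressMessages(
    run_sweep(combos, fx$train, fx$testing, cv, genes)))
  sw2 <- suppressWarnings(suppressMessages(
    run_sweep(rev(combos), fx$train, fx$testing, cv, genes)))
  expect_identical(sw1$winner, sw2$winner)
  lb1 <- sw1$leaderboard[order(sw1$leaderboard$label), ]
  lb2 <- sw2$leaderboard[order(sw2$leaderboard$label), ]
  rownames(lb1) <- rownames(lb2) <- NULL
  expect_equal(lb1, lb2)
  ok <- sw1$leaderboard[sw1$leaderboard$status == "ok", ]
  expect_equal(ok$mean_testing_cindex[1], max(ok$mean_testing_cindex))
})

test_that("median stratification reports protective scores with ties going high", {
  fx <- make_sweep_fixture(seed = 31)
  cv <- cv_plan(5, seed = 31)
  cspec <- enumerate_combinations(list(
    version = 1, pairing = "singles",
    modelers = list(list(family = "Ridge"))))[[1]]
  res <- suppressMessages(run_combination(cspec, fx$train, fx$testing, cv,
                                          rownames(fx$train$expr)))
  strat <- score_and_stratify(res$signature, fx$train)
  expect_setequal(strat$group, c("high", "low"))
  # the sample at the median lands in the high group; odd n -> high majority
  odd <- fx$train
  odd$expr <- odd$expr[, 1:7]; odd$surv <- odd$surv[1:7, ]
  s7 <- score_and_stratify(res$signature, odd)
  expect_equal(sum(s7$group == "high"), 4L)
  # protective orientation: high group should live longer on planted data
  lr <- km_logrank(strat$group, fx$train$surv)
  hi <- strat$group == "high"
  expect_gt(mean(fx$train$surv$time[hi]), mean(fx$train$surv$time[!hi]) * 0.8)
  expect_lt(lr$p, 0.05)
})

test_that("signature archives round-trip predict_scores bit-identically", {
  fx <- make_sweep_fixture(seed = 37)
  cv <- cv_plan(5, seed = 37)
  for (fam in c("Ridge", "RSF", "GBM")) {
    cspec <- enumerate_combinations(list(
      version = 1, pairing = "singles",
      modelers = list(list(family = fam))))[[1]]
    res <- suppressMessages(run_combination(cspec, fx$train, fx$testing, cv,
                                            rownames(fx$train$expr)))
    dir <- file.path(withr::local_tempdir(), fam)
    save_signature(res$signature, dir)
    back <- load_signature(dir)
    expect_identical(predict_scores(back$learner, fx$train),
                     predict_scores(res$signature$learner, fx$train),
                     label = paste(fam, "archive round trip"))
  }
})
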