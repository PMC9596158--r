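# Small in-code fixtures shared across test files.

## deterministic toy cohort: g genes x n samples with exponential survival
toy_cohort <- function(n = 20, g = 5, seed = 1, name = "toy", role = "testing",
                       beta = NULL, censor = 0.3) {
  set.seed(seed)
  expr <- matrix(rnorm(g * n), g, n,
                 dimnames = list(paste0("gene", seq_len(g)),
                                 paste0("s", seq_len(n))))
  lp <- if (is.null(beta)) numeric(n) else drop(crossprod(expr, beta))
  te <- rexp(n, rate = exp(lp))
  tc <- if (censor > 0) rexp(n, rate = censor * exp(mean(lp))) else rep(Inf, n)
  surv <- data.frame(sample_id = colnames(expr),
                     time = pmax(pmin(te, tc), 1e-8),
                     event = as.integer(te <= tc))
  cohort(name, expr, surv, role = role)
}

## single simulated cohort with planted effects, standardized
sim_single_cohort <- function(n = 200, G = 30, planted = c(g0001 = 0.6),
                              seed = 5, censor_target = 0.3) {
  cfg <- sim_config(K = 1, n_per_cohort = n, G = G, planted = planted,
                    batch_shift_sd = 0, batch_scale_range = c(1, 1),
                    censor_target = censor_target, seed = seed)
  standardize(simulate_multicohort(cfg)$multicohort$cohorts[[1]])
}

## brute-force O(n^2) C-index oracle (independent of the implementation)
cindex_oracle <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

## write a cohort pair of TSVs into a temp dir, returning the two paths
write_toy_tsvs <- function(co, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ep <- file.path(dir, paste0(co$name, "_expr.tsv"))
  cp <- file.path(dir, paste0(co$name, "_clin.tsv"))
  write_cohort(co, ep, cp)
  list(expr = ep, clin = cp, dir = dir)
}
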