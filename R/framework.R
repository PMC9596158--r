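# framework: enumerate selector x modeler combinations from a roster file,
# run each on the training cohort, rank by mean held-out C-index over the
# testing cohorts, and emit the winning deployable signature.

expand_roster_entry <- function(entry) {
  family <- entry$family
  if (is.null(family)) cs_stop("roster entry without a family")
  if (identical(family, "Enet")) {
    alphas <- entry$alpha %||% cs_stop("Enet roster entry requires alpha")
    lapply(alphas, function(a) algorithm_spec("Enet", alpha = a))
  } else if (identical(family, "StepCox")) {
    dirs <- entry$direction %||% "both"
    lapply(dirs, function(d) algorithm_spec("StepCox", direction = d))
  } else {
    list(algorithm_spec(family, hyper_grid = entry$hyper_grid %||% list()))
  }
}

#' Enumerate selector x modeler combinations from a roster
#'
#' A roster is a versioned YAML file (or equivalent list) with entries
#' `selectors` and `modelers` (families plus variant expansions: `Enet`
#' takes an `alpha` vector, `StepCox` a `direction` vector) and a `pairing`
#' rule: `"pairs"` pairs every selector with every modeler variant except an
#' identical one; `"singles"` uses the modelers alone. The shipped
#' `roster_default.yaml` yields 76 combinations and `roster_remodel.yaml`
#' the 18 single-model variants; see
#' `system.file("extdata", package = "consurv")`.
#'
#' @param roster Path to a roster YAML file, or a pre-parsed list.
#' @return List of `combination_spec` objects (`selector` possibly NULL,
#'   `modeler`, canonical `label` "Selector + Modeler" or "Modeler").
#' @export
enumerate_combinations <- function(roster) {
  if (is.character(roster)) roster <- yaml::read_yaml(roster)
  if (is.null(roster$version)) cs_stop("roster is missing a version field")
  pairing <- roster$pairing %||% "pairs"
  modelers <- unlist(lapply(roster$modelers, expand_roster_entry), recursive = FALSE)
  combos <- if (identical(pairing, "singles")) {
    lapply(modelers, function(m)
      structure(list(selector = NULL, modeler = m, label = m$label),
                class = "combination_spec"))
  } else if (identical(pairing, "pairs")) {
    selectors <- unlist(lapply(roster$selectors, expand_roster_entry),
                        recursive = FALSE)
    for (s in selectors)
      if (!s$can_select) cs_stop("%s cannot act as a selector", s$label)
    out <- list()
    for (s in selectors) for (m in modelers) {
      if (identical(s$label, m$label)) next
      out[[length(out) + 1L]] <- structure(
        list(selector = s, modeler = m,
             label = paste(s$label, "+", m$label)),
        class = "combination_spec")
    }
    out
  } else cs_stop("unknown pairing rule '%s'", pairing)
  labels <- vapply(combos, `[[`, "", "label")
  if (anyDuplicated(labels))
    cs_stop("duplicate combination labels in roster: %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  combos
}

## path to a shipped roster
roster_path <- function(name = c("default", "remodel")) {
  name <- match.arg(name)
  system.file("extdata", paste0("roster_", name, ".yaml"), package = "consurv",
              mustWork = TRUE)
}

#' Run one selector x modeler combination
#'
#' Fits the selector (when present) on the training cohort restricted to
#' `input_genes`, reduces to the selected genes, fits the modeler on the
#' reduced training cohort, scores training and every testing cohort, and
#' records the per-cohort Harrell C-index (on risk-oriented scores) plus
#' their mean over the testing cohorts only. Failures (e.g. an empty
#' selection) yield a skipped row, never an error.
#'
#' @param cspec A `combination_spec` from [enumerate_combinations()].
#' @param train Standardized training `cohort`.
#' @param testing A `multicohort` of standardized testing cohorts.
#' @param cv A [cv_plan()]; the selector derives its RNG stream from the
#'   selector label and the modeler from the combination label, so sweep
#'   results are independent of execution order.
#' @param input_genes Genes entering the pipeline (e.g. the consensus
#'   screen's selection); must be present in all cohorts.
#' @param cache Optional environment memoizing selector fits across the
#'   combinations of a sweep (a selector's fit does not depend on the
#'   paired modeler, so it is shared).
#' @return List with `row` (leaderboard row as one-row data.frame) and
#'   `signature` (a `signature_model`, or NULL when skipped).
#' @export
run_combination <- function(cspec, train, testing, cv, input_genes, cache = NULL) {
  stopifnot(inherits(cspec, "combination_spec"), inherits(train, "cohort"),
            inherits(testing, "multicohort"))
  skip_row <- function(reason) {
    cs_log("WARNING", cspec$label, paste("skipped:", reason))
    row <- data.frame(label = cspec$label, status = "skipped", reason = reason,
                      n_selected_genes = NA_integer_,
                      mean_testing_cindex = NA_real_, stringsAsFactors = FALSE)
    list(row = row, signature = NULL)
  }
  genes <- input_genes
  sel_fit <- NULL
  if (!is.null(cspec$selector)) {
    sel_key <- cspec$selector$label
    if (!is.null(cache) && !is.null(cache[[sel_key]])) {
      sel_fit <- cache[[sel_key]]
    } else {
      cv_sel <- cv_plan(cv$folds, derive_seed(cv$seed, sel_key))
      sel_fit <- tryCatch(
        fit_learner(cspec$selector, subset_genes(train, input_genes), cv_sel),
        error = function(e) e)
      if (!is.null(cache)) cache[[sel_key]] <- sel_fit
    }
    if (inherits(sel_fit, "error")) return(skip_row(conditionMessage(sel_fit)))
    genes <- tryCatch(select_features(sel_fit), error = function(e) e)
    if (inherits(genes, "error")) return(skip_row(conditionMessage(genes)))
  }
  cv_mod <- cv_plan(cv$folds, derive_seed(cv$seed, cspec$label))
  mod_fit <- tryCatch(
    fit_learner(cspec$modeler, subset_genes(train, genes), cv_mod),
    error = function(e) e)
  if (inherits(mod_fit, "error")) return(skip_row(conditionMessage(mod_fit)))
  cohorts <- c(list(train), unname(testing$cohorts))
  cvec <- vapply(cohorts, function(co) {
    sc <- predict_scores(mod_fit, subset_genes(co, genes))
    cindex_quick(as_risk(sc), co$surv$time, co$surv$event)
  }, 0)
  names(cvec) <- vapply(cohorts, `[[`, "", "name")
  test_idx <- -1L
  mean_test <- mean(cvec[test_idx], na.rm = TRUE)
  sig_genes <- if (length(mod_fit$selected_genes)) mod_fit$selected_genes else genes
  row <- data.frame(label = cspec$label, status = "ok", reason = "",
                    n_selected_genes = length(sig_genes),
                    mean_testing_cindex = mean_test, stringsAsFactors = FALSE)
  for (nm in names(cvec)) row[[paste0("c_", nm)]] <- cvec[[nm]]
  sig <- structure(list(genes = sig_genes, learner = mod_fit,
                        orientation = mod_fit$orientation,
                        provenance = list(label = cspec$label,
                                          selector = cspec$selector$label,
                                          cv_seed = cv$seed, folds = cv$folds)),
                   class = "signature_model")
  list(row = row, signature = sig)
}

#' Rank combination rows into a leaderboard
#'
#' Descending by mean testing C-index; ties broken by fewer selected genes,
#' then label lexicographically. The training-cohort C-index is reported but
#' never enters the ranking.
#'
#' @param rows data.frame of rows from [run_combination()] (rbind-ed).
#' @return The ranked data.frame with attribute `winner` (top label).
#' @export
build_leaderboard <- function(rows) {
  ok <- rows[rows$status == "ok" & is.finite(rows$mean_testing_cindex), , drop = FALSE]
  if (nrow(ok) == 0) cs_stop("all combinations were skipped")
  skipped <- rows[rows$status != "ok" | !is.finite(rows$mean_testing_cindex), , drop = FALSE]
  ord <- order(-ok$mean_testing_cindex, ok$n_selected_genes, ok$label,
               method = "radix")
  out <- rbind(ok[ord, , drop = FALSE], skipped)
  rownames(out) <- NULL
  attr(out, "winner") <- out$label[1]
  out
}

#' Run a full combination sweep
#'
#' Executes every combination, builds the leaderboard, and refits the
#' winning combination (same derived seeds, hence identical) to return its
#' deployable signature.
#'
#' @inheritParams run_combination
#' @param combos List from [enumerate_combinations()].
#' @return List with `leaderboard`, `winner` (label) and `signature`
#'   (the winning `signature_model`).
#' @export
run_sweep <- function(combos, train, testing, cv, input_genes) {
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    cs_log("INFO", "sweep", sprintf("[%d/%d] %s", i, length(combos), combos[[i]]$label))
    rows[[i]] <- suppressMessages(
      run_combination(combos[[i]], train, testing, cv, input_genes, cache))$row
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- do.call(rbind, lapply(rows, function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA_real_
    r[all_cols]
  }))
  lb <- build_leaderboard(rows)
  winner <- attr(lb, "winner")
  wspec <- combos[[match(winner, vapply(combos, `[[`, "", "label"))]]
  sig <- suppressMessages(
    run_combination(wspec, train, testing, cv, input_genes, cache))$signature
  list(leaderboard = lb, winner = winner, signature = sig)
}

#' Score a cohort with a signature and stratify at the median
#'
#' Scores are reported in protective orientation (higher score = longer
#' expected survival); samples at or above the within-cohort median score
#' form the `"high"` group.
#'
#' @param sig A `signature_model`.
#' @param cohort A `cohort` containing the signature genes.
#' @return data.frame with `sample_id`, `score` (protective orientation),
#'   `group` (`"high"`/`"low"`).
#' @export
score_and_stratify <- function(sig, cohort) {
  stopifnot(inherits(sig, "signature_model"), inherits(cohort, "cohort"))
  sc <- predict_scores(sig$learner, cohort)
  protective <- if (identical(sig$orientation, "higher_is_protective"))
    as.numeric(sc) else -as.numeric(sc)
  med <- stats::median(protective)
  group <- ifelse(protective >= med, "high", "low")
  if (all(group == "high"))
    cs_log("WARNING", "score_and_stratify", "all scores equal; single group")
  data.frame(sample_id = cohort$surv$sample_id, score = protective,
             group = group, stringsAsFactors = FALSE)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model '%s': %d genes, %s orientation>\n",
              x$provenance$label, length(x$genes), x$orientation))
  invisible(x)
}

#' Write a leaderboard to TSV
#'
#' @param lb Leaderboard data.frame.
#' @param path Output file.
#' @export
write_leaderboard <- function(lb, path) {
  utils::write.table(lb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(lb)
}
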