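# cohort_io: read, validate, harmonize and standardize multi-cohort
# expression + survival data.
#
# An expression matrix is a base numeric matrix, genes as rows (rownames =
# gene ids), samples as columns (colnames = sample ids), log-scale values.
# A survival table is a data.frame with columns sample_id, time, event and
# optional covariate columns.

validate_expression <- function(values, context = "expression") {
  if (!is.matrix(values) || !is.numeric(values))
    cs_stop("%s: expected a numeric matrix", context)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    cs_stop("%s: gene (row) and sample (column) names are required", context)
  if (anyDuplicated(rownames(values)))
    cs_stop("%s: duplicate gene ids: %s", context,
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    cs_stop("%s: duplicate sample ids: %s", context,
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    cs_stop("%s: non-finite or missing values present; impute upstream", context)
  values
}

validate_survival <- function(surv, context = "survival") {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(surv))
  if (length(miss))
    cs_stop("%s: missing required columns: %s", context, paste(miss, collapse = ", "))
  surv$sample_id <- as.character(surv$sample_id)
  if (anyDuplicated(surv$sample_id))
    cs_stop("%s: duplicate sample ids: %s", context,
            paste(unique(surv$sample_id[duplicated(surv$sample_id)]), collapse = ", "))
  bad_t <- which(!is.finite(surv$time) | surv$time <= 0)
  if (length(bad_t))
    cs_stop("%s: nonpositive or missing time in rows: %s", context,
            paste(bad_t, collapse = ", "))
  bad_e <- which(!(surv$event %in% c(0, 1)))
  if (length(bad_e))
    cs_stop("%s: event not in {0,1} in rows: %s", context, paste(bad_e, collapse = ", "))
  surv
}

#' Construct a cohort
#'
#' Bundles an expression matrix (genes x samples, log scale) with a survival
#' table, inner-joining on sample id and validating both parts.
#'
#' @param name Cohort name.
#' @param expr Numeric matrix, genes as rows, samples as columns.
#' @param surv data.frame with columns `sample_id`, `time` (> 0, one declared
#'   unit per run, conventionally months), `event` (0/1), plus optional
#'   covariate columns which are preserved.
#' @param role One of `"training"`, `"testing"`, `"external"`.
#' @return An object of class `cohort`: list with `name`, `role`, `expr`,
#'   `surv` (row order matching `colnames(expr)`).
#' @export
cohort <- function(name, expr, surv, role = c("testing", "training", "external")) {
  role <- match.arg(role)
  expr <- validate_expression(expr, paste0(name, " expression"))
  surv <- validate_survival(surv, paste0(name, " survival"))
  shared <- intersect(colnames(expr), surv$sample_id)
  if (length(shared) == 0L)
    cs_stop("%s: zero overlapping samples between expression and survival", name)
  dropped <- (ncol(expr) - length(shared)) + (nrow(surv) - length(shared))
  if (dropped > 0)
    cs_log("WARNING", name, sprintf("%d sample(s) dropped (unmatched between tables)", dropped))
  expr <- expr[, shared, drop = FALSE]
  surv <- surv[match(shared, surv$sample_id), , drop = FALSE]
  rownames(surv) <- NULL
  if (length(shared) < 2L) cs_stop("%s: fewer than 2 samples after join", name)
  if (sum(surv$event) < 1L) cs_stop("%s: cohort has no events", name)
  structure(list(name = name, role = role, expr = expr, surv = surv),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s' (%s): %d genes x %d samples, %d events>\n",
              x$name, x$role, nrow(x$expr), ncol(x$expr), sum(x$surv$event)))
  invisible(x)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) cs_stop("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}

#' Read a cohort from expression and clinical files
#'
#' Expression: TSV/CSV, first column gene id, remaining columns samples.
#' Clinical: TSV/CSV with required columns `sample_id`, `time`, `event`;
#' extra columns are kept as covariates. Samples present in only one table
#' are dropped with a warning.
#'
#' @param expr_path,clin_path File paths (`.csv` parsed comma-separated,
#'   anything else tab-separated).
#' @param name Cohort name.
#' @param role Cohort role (see [cohort()]).
#' @return A `cohort`.
#' @export
read_cohort <- function(expr_path, clin_path, name,
                        role = c("testing", "training", "external")) {
  etab <- read_table_auto(expr_path)
  genes <- as.character(etab[[1]])
  expr <- as.matrix(etab[, -1, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- genes
  clin <- read_table_auto(clin_path)
  cohort(name, expr, clin, role = match.arg(role))
}

#' Write a cohort to expression and clinical files
#'
#' Inverse of [read_cohort()]; same TSV/CSV dialect ('.' decimal separator,
#' UTF-8).
#'
#' @param x A `cohort`.
#' @param expr_path,clin_path Output paths.
#' @export
write_cohort <- function(x, expr_path, clin_path) {
  stopifnot(inherits(x, "cohort"))
  sep_e <- if (grepl("\\.csv$", expr_path, ignore.case = TRUE)) "," else "\t"
  etab <- data.frame(gene_id = rownames(x$expr), x$expr, check.names = FALSE)
  utils::write.table(etab, expr_path, sep = sep_e, row.names = FALSE, quote = FALSE)
  sep_c <- if (grepl("\\.csv$", clin_path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x$surv, clin_path, sep = sep_c, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Intersect cohorts onto a shared gene space
#'
#' Restricts every cohort to the genes common to all, preserving the gene
#' order of the first cohort.
#'
#' @param cohorts List of `cohort` objects (>= 2).
#' @return A `multicohort`: list with `cohorts` (named list) and
#'   `shared_genes`.
#' @export
intersect_genes <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2L)
  lapply(cohorts, function(x) stopifnot(inherits(x, "cohort")))
  shared <- rownames(cohorts[[1]]$expr)
  for (x in cohorts[-1]) shared <- shared[shared %in% rownames(x$expr)]
  if (length(shared) == 0L) cs_stop("gene intersection across cohorts is empty")
  cohorts <- lapply(cohorts, function(x) {
    x$expr <- x$expr[shared, , drop = FALSE]
    x
  })
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  structure(list(cohorts = cohorts, shared_genes = shared), class = "multicohort")
}

#' @export
print.multicohort <- function(x, ...) {
  cat(sprintf("<multicohort: %d cohorts, %d shared genes>\n",
              length(x$cohorts), length(x$shared_genes)))
  for (co in x$cohorts) print(co)
  invisible(x)
}

#' Standardize a cohort gene-wise
#'
#' Centers and scales each gene row to mean 0, sd 1 within the cohort.
#' Genes with zero variance are set to all-zero and recorded in the
#' `constant_genes` attribute.
#'
#' @param x A `cohort` with >= 2 samples.
#' @return The standardized `cohort`.
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "cohort"), ncol(x$expr) >= 2L)
  m <- rowMeans(x$expr)
  centered <- x$expr - m
  s <- sqrt(rowSums(centered^2) / (ncol(x$expr) - 1L))
  const <- s == 0
  s[const] <- 1
  x$expr <- centered / s
  x$expr[const, ] <- 0
  attr(x, "constant_genes") <- rownames(x$expr)[const]
  x
}

#' Assemble a meta-cohort
#'
#' Standardizes every cohort gene-wise (a location/scale batch adjustment)
#' and concatenates samples. Sample ids repeated across cohorts are kept
#' once (first occurrence in cohort order). Only covariate columns common to
#' all cohorts are retained.
#'
#' @param mc A `multicohort`.
#' @return A `cohort` named `"Meta"` with role `"testing"`.
#' @export
assemble_meta <- function(mc) {
  stopifnot(inherits(mc, "multicohort"))
  std <- lapply(mc$cohorts, standardize)
  common_cols <- Reduce(intersect, lapply(std, function(x) names(x$surv)))
  expr <- do.call(cbind, lapply(std, `[[`, "expr"))
  surv <- do.call(rbind, lapply(std, function(x) x$surv[, common_cols, drop = FALSE]))
  dup <- duplicated(surv$sample_id)
  if (any(dup))
    cs_log("WARNING", "Meta", sprintf("%d repetition(s) removed (duplicate sample ids)", sum(dup)))
  expr <- expr[, !dup, drop = FALSE]
  colnames(expr) <- surv$sample_id[!dup]
  surv <- surv[!dup, , drop = FALSE]
  cohort("Meta", expr, surv, role = "testing")
}

#' Subset a cohort to a gene list
#'
#' @param x A `cohort`.
#' @param genes Character vector of gene ids; all must be present.
#' @return The restricted `cohort`.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "cohort"))
  missing <- setdiff(genes, rownames(x$expr))
  if (length(missing))
    cs_stop("cohort '%s' is missing gene(s): %s", x$name, paste(missing, collapse = ", "))
  x$expr <- x$expr[genes, , drop = FALSE]
  x
}
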