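# Readers and writers for study bundles (expression matrix + survival table)
# and per-gene result tables.

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Load a study: expression matrix plus survival table
#'
#' Reads a TSV/CSV expression matrix (first column gene id, remaining columns
#' samples) and a TSV/CSV survival table (columns `sample`, `time`, `event`),
#' reconciles samples by id (not position), and reports the samples dropped
#' for lacking a counterpart.
#'
#' @param expr_path,surv_path Paths to the two files; `.csv` is read
#'   comma-separated, anything else tab-separated.
#' @param transpose Set to `TRUE` when the expression file has samples as
#'   rows and genes as columns.
#' @return An object of class `"study_bundle"`: a list with `expression`
#'   (numeric matrix, genes x samples), `survival` (tibble with `sample`,
#'   `time`, `event`), and `dropped` (list with `expr_only`, `surv_only`
#'   sample ids).
#' @export
load_study <- function(expr_path, surv_path, transpose = FALSE) {
  expr_df <- read_delim_auto(expr_path)
  surv <- read_delim_auto(surv_path)
  req <- c("sample", "time", "event")
  if (!all(req %in% names(surv))) {
    abort(paste0(
      "survival table must have columns sample, time, event; found: ",
      paste(names(surv), collapse = ", ")
    ))
  }
  surv$sample <- as.character(surv$sample)
  if (anyDuplicated(surv$sample)) {
    abort("duplicate sample ids in the survival table.")
  }
  surv$time <- as.numeric(surv$time)
  bad_ev <- !surv$event %in% c(0, 1)
  if (any(bad_ev)) {
    abort(paste0(
      "non-binary event codes for sample(s): ",
      paste(utils::head(surv$sample[bad_ev], 5), collapse = ", ")
    ))
  }
  surv$event <- as.numeric(surv$event)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- as.character(expr_df[[1]])
  if (transpose) expr <- t(expr)
  if (anyDuplicated(colnames(expr))) {
    abort("duplicate sample ids in the expression matrix.")
  }
  storage.mode(expr) <- "double"
  common <- intersect(colnames(expr), surv$sample)
  if (length(common) == 0) {
    abort("zero overlapping samples between expression and survival files.")
  }
  dropped <- list(
    expr_only = setdiff(colnames(expr), common),
    surv_only = setdiff(surv$sample, common)
  )
  n_drop <- length(dropped$expr_only) + length(dropped$surv_only)
  if (n_drop > 0) {
    inform(paste0(
      "dropped ", n_drop, " unmatched sample(s): ",
      paste(c(dropped$expr_only, dropped$surv_only), collapse = ", ")
    ))
  }
  structure(
    list(
      expression = expr[, common, drop = FALSE],
      survival = as_tibble(surv[match(common, surv$sample), req]),
      dropped = dropped
    ),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "Study bundle: %d genes x %d samples, %d events\n",
    nrow(x$expression), ncol(x$expression), sum(x$survival$event)
  ))
  invisible(x)
}

#' Write a per-gene result table
#'
#' Writes a TSV with a fixed column order (as computed), numeric columns
#' rounded to 6 significant digits, rows sorted by `index` descending with
#' gene id as a stable tie-break (falls back to gene id only when no `index`
#' column is present).
#'
#' @param results Data frame of per-gene results (e.g. from
#'   [separability_screen()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  if ("index" %in% names(results) && nrow(results) > 0) {
    results <- results[order(-xtfrm(results$index), results$gene), ]
  } else if ("gene" %in% names(results) && nrow(results) > 0) {
    results <- results[order(results$gene), ]
  }
  results <- dplyr::mutate(
    results,
    dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6))
  )
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}

#' Write a simulated study to disk as a fixture
#'
#' Writes `expr.tsv` (first column `gene`), `surv.tsv` (`sample`, `time`,
#' `event`) and `truth.tsv` per study directory, the on-disk layout expected
#' by [load_study()].
#'
#' @param example A [simulate_meta_example()] object.
#' @param out_dir Output directory (one subdirectory per study).
#' @return `out_dir`, invisibly.
#' @export
write_meta_example <- function(example, out_dir) {
  stopifnot(inherits(example, "meta_example"))
  for (nm in names(example$studies)) {
    dir <- file.path(out_dir, nm)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    st <- example$studies[[nm]]
    expr <- dplyr::bind_cols(
      tibble(gene = rownames(st$expression)),
      as_tibble(st$expression)
    )
    readr::write_tsv(expr, file.path(dir, "expr.tsv"), progress = FALSE)
    readr::write_tsv(
      st$survival[, c("sample", "time", "event")],
      file.path(dir, "surv.tsv"), progress = FALSE
    )
  }
  readr::write_tsv(example$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}
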