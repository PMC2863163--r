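# Per-gene screening of an expression matrix against a survival table.

#' Screen every gene of an expression matrix with the separability index
#'
#' Computes, for each gene (row) of `expr`, the separability index, its
#' components, the robust score test, and optionally the four
#' likelihood-based comparison indices and the likelihood-ratio statistic.
#' Samples are matched between `expr` columns and `surv$sample` by name;
#' genes with missing values are dropped with a message.
#'
#' @param expr Numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames, or a data frame whose first column holds gene
#'   ids.
#' @param surv A data frame with columns `sample`, `time`, `event`.
#' @param with_comparisons Also compute the Allison, modified Allison,
#'   Nagelkerke and Xu--O'Quigley indices and the LR statistic per gene.
#' @param add_q_values Append Storey q-values computed on the robust score
#'   p-values (and on the LR p-values when `with_comparisons = TRUE`).
#' @return A tibble with one row per retained gene: `gene`, `delta0`, `dmax`,
#'   `index`, `direction`, `score_stat`, `p_value`, `q_value`, and with
#'   `with_comparisons` also `beta_hat`, `lr_statistic`, `lr_p_value`,
#'   `lr_q_value`, `allison`, `allison_modified`, `nagelkerke`,
#'   `xu_oquigley`. Genes whose covariate is constant on every risk set are
#'   returned with `NA` index columns.
#' @examples
#' ex <- simulate_meta_example(n = c(40, 20), n_genes = 50, seed = 1)
#' head(separability_screen(ex$studies[[1]]$expression,
#'                          ex$studies[[1]]$survival))
#' @export
separability_screen <- function(expr, surv, with_comparisons = FALSE,
                                add_q_values = TRUE) {
  if (is.data.frame(expr)) {
    genes <- as.character(expr[[1]])
    expr <- as.matrix(expr[, -1, drop = FALSE])
    rownames(expr) <- genes
  }
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("g%04d", seq_len(nrow(expr)))
  }
  req <- c("sample", "time", "event")
  if (!all(req %in% names(surv))) {
    abort("`surv` must have columns sample, time, event.")
  }
  if (!is.null(colnames(expr))) {
    common <- intersect(colnames(expr), as.character(surv$sample))
    if (length(common) == 0) {
      abort("no overlapping samples between `expr` and `surv`.")
    }
    expr <- expr[, common, drop = FALSE]
    surv <- surv[match(common, as.character(surv$sample)), ]
  } else if (ncol(expr) != nrow(surv)) {
    abort("`expr` has no sample names and its column count differs from `surv`.")
  }
  has_na <- apply(expr, 1, anyNA)
  if (any(has_na)) {
    inform(paste0("dropping ", sum(has_na), " gene(s) with missing values."))
    expr <- expr[!has_na, , drop = FALSE]
  }
  dc <- rs_decomp(surv$time, surv$event)
  one_gene <- function(z) {
    sep <- tryCatch(sep_core(dc, z), error = function(e) NULL)
    if (is.null(sep)) {
      out <- c(delta0 = NA_real_, dmax = NA_real_, index = NA_real_,
               direction = NA_real_, score_stat = NA_real_,
               p_value = NA_real_)
    } else {
      out <- c(delta0 = sep$delta0, dmax = sep$dmax, index = sep$index,
               direction = sep$direction, score_stat = sep$score_stat,
               p_value = sep$p_value)
    }
    if (with_comparisons) {
      fit <- tryCatch(fit_cox_core(dc, z[dc$ord]), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        out <- c(out, beta_hat = NA_real_, lr_statistic = NA_real_,
                 allison = NA_real_, allison_modified = NA_real_,
                 nagelkerke = NA_real_, xu_oquigley = NA_real_)
      } else {
        allison <- 1 - exp(-fit$lr / dc$n_subjects)
        fitobj <- structure(
          list(beta = fit$beta, converged = TRUE, decomp = dc,
               z_sorted = z[dc$ord], lr_statistic = fit$lr),
          class = "sep_coxfit"
        )
        out <- c(
          out, beta_hat = fit$beta, lr_statistic = fit$lr,
          allison = allison,
          allison_modified = 1 - exp(-fit$lr / dc$n_events),
          nagelkerke = allison /
            (1 - exp(2 * fit$loglik_null / dc$n_subjects)),
          xu_oquigley = xu_oquigley_index(fitobj)
        )
      }
    }
    out
  }
  vals <- t(apply(expr, 1, one_gene))
  out <- dplyr::bind_cols(tibble(gene = rownames(expr)), as_tibble(vals))
  out$direction <- dplyr::if_else(out$direction > 0, "HR>1", "HR<1")
  if (add_q_values) {
    out$q_value <- q_values(out$p_value)
    if (with_comparisons) {
      out$lr_p_value <- pchisq(out$lr_statistic, 1, lower.tail = FALSE)
      out$lr_q_value <- q_values(out$lr_p_value)
    }
  }
  out
}
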