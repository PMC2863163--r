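# Two-study synthetic gene-expression generator: block-structured log-normal
# expression with clumpy dependence, risk-group survival, calibrated uniform
# censoring, and quantile normalization.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' after normalization the sorted values of each column equal the row-wise
#' mean of the sorted columns, with ties receiving the mean of the tied
#' reference quantiles. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix, genes in rows, samples in columns; no missing
#'   values.
#' @return A matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) abort("`x` must not contain missing values.")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

# gene-block boundaries; the reference design is (50, 100, 150, 250, 350)
# at 1,000 genes and scales proportionally for smaller fixtures
meta_blocks <- function(n_genes) {
  cuts <- round(n_genes * c(0.05, 0.10, 0.15, 0.25, 0.35))
  cuts <- pmax(cuts, seq_along(cuts)) # keep blocks non-empty at tiny sizes
  cuts
}

# block-structured log-normal expression for one study; genes in rows
meta_expression <- function(n, n_genes, rho) {
  low <- seq_len(n %/% 2) # low-risk subjects occupy the first half
  cuts <- meta_blocks(n_genes)
  mu <- matrix(0, nrow = n_genes, ncol = n)
  mu[1:cuts[1], low] <- 4
  mu[(cuts[1] + 1):cuts[2], low] <- 3
  # structured non-prognostic blocks: one random subject subset per block,
  # independent of risk group
  blocks <- list(
    list(genes = (cuts[2] + 1):cuts[3], frac = 0.4, mean = 1),
    list(genes = (cuts[3] + 1):cuts[4], frac = 0.5, mean = 0.5),
    list(genes = (cuts[4] + 1):cuts[5], frac = 0.7, mean = 0.1)
  )
  for (b in blocks) {
    subset <- sample.int(n, round(b$frac * n))
    mu[b$genes, subset] <- b$mean
  }
  z <- matrix(exp(rnorm(n_genes * n, mean = mu, sd = 1.5)),
              nrow = n_genes, ncol = n)
  # clumpy dependence: shared log-normal subject factor per 10-gene block
  n_blocks <- n_genes %/% 10
  shared <- matrix(exp(rnorm(n_blocks * n)), nrow = n_blocks, ncol = n)
  z <- z + rho * shared[rep(seq_len(n_blocks), each = 10), , drop = FALSE]
  dimnames(z) <- list(
    sprintf("g%04d", seq_len(n_genes)),
    sprintf("s%03d", seq_len(n))
  )
  z
}

meta_survival <- function(n, effect, model, censor_par) {
  xi <- rep(c(0, log(effect)), c(n %/% 2, n - n %/% 2))
  t_surv <- draw_survival(xi, 1, model = model)
  cns <- runif(n, 0, censor_par)
  tibble(
    sample = sprintf("s%03d", seq_len(n)),
    time = pmin(t_surv, cns),
    event = as.numeric(t_surv <= cns),
    risk_group = rep(c("low", "high"), c(n %/% 2, n - n %/% 2))
  )
}

#' Simulate the two-study meta-selection example
#'
#' Generates two studies (default sizes 150 and 50) of 1,000 genes each.
#' Subjects split into a low-risk half (\eqn{\xi = 0}) and a high-risk half
#' (\eqn{e^\xi =} `effect`), with survival from \eqn{S(t) = \exp(-t e^\xi)}
#' (`"ph"`) or \eqn{S(t) = (1 + t e^\xi)^{-1}} (`"po"`) and uniform censoring
#' calibrated to an expected fraction `p_c`. Expression is block-structured
#' log-normal: genes 1--50 and 51--100 are over-expressed in the low-risk
#' group (meanlog 4 and 3 vs 0; the truly prognostic set), genes 101--150,
#' 151--250, 251--350 are differentially expressed along random binary
#' factors unlinked to risk (meanlog 1/0.5/0.1 for 40/50/70% of subjects),
#' genes 351--1,000 are pure noise (meanlog 0; sdlog 1.5 throughout).
#' Clumpy dependence is added per 10-gene block through a shared standard
#' log-normal subject factor scaled by `rho`, and each study is
#' quantile-normalized.
#'
#' @param effect High-risk effect size \eqn{e^\xi} (3 or 5 in the reference
#'   design).
#' @param model `"ph"` or `"po"`.
#' @param rho Clumpy-dependence strength (0.25, 0.5 or 0.75 in the reference
#'   design).
#' @param n Integer vector of study sizes.
#' @param n_genes Number of genes (multiple of 10).
#' @param p_c Expected censoring fraction.
#' @param seed Optional integer seed.
#' @return An object of class `"meta_example"`: a list with `studies` (a list
#'   of per-study lists holding `expression` -- genes x samples matrix -- and
#'   `survival` -- a tibble with `sample`, `time`, `event`, `risk_group`) and
#'   `truth` (a tibble with `gene`, `prognostic`).
#' @examples
#' ex <- simulate_meta_example(effect = 5, n = c(30, 20), n_genes = 100,
#'                             seed = 1)
#' sapply(ex$studies, function(s) dim(s$expression))
#' @export
simulate_meta_example <- function(effect = 5, model = c("ph", "po"),
                                  rho = 0.5, n = c(150, 50), n_genes = 1000,
                                  p_c = 0.3, seed = NULL) {
  model <- sim_model(model[1])
  stopifnot(effect > 0, rho >= 0, all(n >= 4), n_genes %% 10 == 0,
            n_genes >= 10)
  censor_par <- solve_censoring_parameter(
    p_c, mechanism = "uniform", model = model, beta = log(effect),
    covariate = "bernoulli"
  )
  gen <- function() {
    studies <- lapply(n, function(ni) {
      expr <- quantile_normalize(meta_expression(ni, n_genes, rho))
      list(
        expression = expr,
        survival = meta_survival(ni, effect, model, censor_par)
      )
    })
    names(studies) <- paste0("study_", seq_along(n))
    truth <- tibble(
      gene = sprintf("g%04d", seq_len(n_genes)),
      prognostic = seq_len(n_genes) <= meta_blocks(n_genes)[2]
    )
    structure(
      list(studies = studies, truth = truth,
           config = list(effect = effect, model = model, rho = rho,
                         n = n, n_genes = n_genes, p_c = p_c)),
      class = "meta_example"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' @export
print.meta_example <- function(x, ...) {
  cat(sprintf(
    "Synthetic meta-selection example: %d studies (n = %s), %d genes, %s model, e^xi = %g, rho = %g\n",
    length(x$studies), paste(x$config$n, collapse = ", "),
    x$config$n_genes, toupper(x$config$model), x$config$effect, x$config$rho
  ))
  invisible(x)
}
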