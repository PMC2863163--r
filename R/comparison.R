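# Four likelihood-based predictive-accuracy indices computed at the Cox MLE:
# Allison, modified Allison, Nagelkerke, Xu-O'Quigley.

#' Likelihood-ratio based predictive-accuracy indices
#'
#' Given a converged one-covariate Cox fit with likelihood-ratio statistic
#' \eqn{LR = 2(\ell(\hat\beta) - \ell(0))}:
#' * Allison: \eqn{1 - \exp(-LR/n)};
#' * modified Allison: \eqn{1 - \exp(-LR/k)} with \eqn{k} the total number of
#'   failures (less sensitive to censoring than the original);
#' * Nagelkerke: Allison divided by its maximum
#'   \eqn{R^2_{max} = 1 - \exp(2\ell(0)/n)}, so the range \eqn{[0, 1]} is
#'   fully exploited.
#'
#' @param fit A [cox_fit()] object.
#' @return A one-row tibble with columns `allison`, `allison_modified`,
#'   `nagelkerke` (all `NA` if the fit did not converge).
#' @export
likelihood_ratio_indices <- function(fit) {
  stopifnot(inherits(fit, "sep_coxfit"))
  if (!fit$converged) {
    return(tibble(
      allison = NA_real_, allison_modified = NA_real_, nagelkerke = NA_real_
    ))
  }
  lr <- fit$lr_statistic
  allison <- 1 - exp(-lr / fit$n)
  r2max <- 1 - exp(2 * fit$loglik_null / fit$n)
  tibble(
    allison = allison,
    allison_modified = 1 - exp(-lr / fit$n_events),
    nagelkerke = allison / r2max
  )
}

#' Xu--O'Quigley predictive-accuracy index
#'
#' A transformation of the Kullback--Leibler divergence between the fitted and
#' the null conditional probabilities of failure. With
#' \eqn{\pi_i(\beta, t_j) = e^{\beta z_i} / \sum_{l \in R_j} e^{\beta z_l}}
#' (the conditional probability that subject \eqn{i} is selected for failure
#' at \eqn{t_j}),
#' \eqn{\Gamma = \sum_j \hat w_j \sum_{i \in R_j} \pi_i(\hat\beta, t_j)
#' \log[\pi_i(\hat\beta, t_j) / \pi_i(0, t_j)]}, where the weights
#' \eqn{\hat w_j} are the jumps of the Kaplan--Meier estimator of the
#' distribution function of the survival time, renormalized to sum to one
#' over the observed failure times. The index is \eqn{1 - \exp(-2\Gamma)}.
#'
#' @param fit A [cox_fit()] object.
#' @return A length-one numeric (`NA` if the fit did not converge).
#' @export
xu_oquigley_index <- function(fit) {
  stopifnot(inherits(fit, "sep_coxfit"))
  if (!fit$converged) return(NA_real_)
  dc <- fit$decomp
  zs <- fit$z_sorted
  fail <- dc$d > 0L
  # Kaplan-Meier jumps of the distribution of T at the distinct failure times
  surv <- cumprod(1 - dc$d / dc$n)
  jump <- c(1, surv[-dc$N]) - surv
  wt <- jump[fail] / sum(jump[fail])
  # KL_j = sum_{i in R_j} pi_i(b) * (a_i - log S0_j + log n_j), via suffix sums
  a <- fit$beta * zs
  m <- max(a)
  ea <- exp(a - m)
  s0 <- revcumsum(ea)[dc$first]
  t1 <- revcumsum(a * ea)[dc$first]
  kl <- t1 / s0 - (m + log(s0)) + log(dc$n)
  gamma <- sum(wt * kl[fail])
  1 - exp(-2 * max(0, gamma))
}

#' All four comparison indices for one covariate
#'
#' Fits the one-covariate Cox model and evaluates the Allison, modified
#' Allison, Nagelkerke and Xu--O'Quigley indices at the MLE.
#'
#' @inheritParams breslow_loglik
#' @return A one-row tibble with columns `beta_hat`, `lr_statistic`,
#'   `converged`, `allison`, `allison_modified`, `nagelkerke`, `xu_oquigley`.
#' @examples
#' d <- simulate_survival(200, hr = 2, seed = 1)
#' comparison_indices(d, z)
#' @export
comparison_indices <- function(data, covariate, time = time, event = event) {
  fit <- cox_fit(data, {{ covariate }}, time = {{ time }}, event = {{ event }})
  dplyr::bind_cols(
    tibble(
      beta_hat = fit$beta, lr_statistic = fit$lr_statistic,
      converged = fit$converged
    ),
    likelihood_ratio_indices(fit),
    tibble(xu_oquigley = xu_oquigley_index(fit))
  )
}
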