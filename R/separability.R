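# The separability index: null-score components U_j, robust components W_j,
# the theoretical maximum Dmax, and the robust score test.

# core computation shared by separability_index() and the per-gene screen;
# dc is an rs_decomp() list, z in original subject order
sep_core <- function(dc, z, need_index = TRUE) {
  zs <- z[dc$ord]
  sum_d_z <- as.vector(rowsum(zs * dc$status, dc$block))
  zbar <- revcumsum(zs)[dc$first] / dc$n
  u <- sum_d_z - dc$d * zbar
  # Lin-Wei robust components aggregated over the subjects exiting at t_j:
  # W_j = U_j - sum_{t_l <= t_j} (d_l/n_l) * sum_{i in E_j} (z_i - zbar_l)
  sum_e_z <- as.vector(rowsum(zs, dc$block))
  dn <- dc$d / dc$n
  w <- u - (sum_e_z * cumsum(dn) - dc$e * cumsum(dn * zbar))
  delta0 <- sum(u)
  if (!need_index) {
    return(list(u = u, w = w, delta0 = delta0))
  }
  dir <- if (delta0 < 0) -1 else 1
  dmax <- dmax_core(dc, zs, zbar, dir)
  s0 <- delta0^2 / sum(w^2)
  list(
    u = u, w = w, delta0 = delta0, dmax = dmax,
    index = abs(delta0) / dmax, direction = dir, score_stat = s0,
    p_value = pchisq(s0, 1, lower.tail = FALSE)
  )
}

# Dmax: at each failure time the d_j failing subjects are replaced by the d_j
# members of R_j with the most extreme covariate values in direction `dir`
# (the beta -> +/-infinity limit conditioned on the observed risk sets).
dmax_core <- function(dc, zs, zbar, dir) {
  zd <- dir * zs
  fail <- dc$d > 0L
  if (all(dc$d <= 1L)) {
    suffix_max <- rev(cummax(rev(zd)))[dc$first]
    dmax <- sum((suffix_max - dir * zbar)[fail])
  } else {
    n_tot <- dc$n_subjects
    dmax <- sum(vapply(which(fail), function(j) {
      top <- sort(zd[dc$first[j]:n_tot], decreasing = TRUE)[seq_len(dc$d[j])]
      sum(top) - dc$d[j] * dir * zbar[j]
    }, numeric(1)))
  }
  if (dmax <= .Machine$double.eps^0.5 * max(1, max(abs(zs)))) {
    abort("zero separability scale: covariate is constant on every risk set with a failure.")
  }
  dmax
}

#' Null score components U_j at each distinct time
#'
#' \eqn{U_j = \sum_{i \in D_j} z_i - d_j \bar z_{R_j}}: the score contribution
#' of the j-th distinct time evaluated at \eqn{\beta = 0}. Equivalently
#' \eqn{U_j = d_j (n_j - d_j) / n_j (\bar z_{D_j} - \bar z_{R^*_j})}, a scaled
#' difference between the mean covariate of the subjects failing at
#' \eqn{t_j} and of those at risk but not failing. \eqn{\sum_j U_j} equals the
#' Breslow score at \eqn{\beta = 0}.
#'
#' @inheritParams breslow_loglik
#' @return A tibble with columns `time`, `n_fail`, `u`.
#' @export
score_components <- function(data, covariate, time = time, event = event) {
  dc <- rs_decomp(dplyr::pull(data, {{ time }}), dplyr::pull(data, {{ event }}))
  res <- sep_core(dc, pull_z(data, {{ covariate }}), need_index = FALSE)
  tibble(time = dc$tj, n_fail = as.integer(dc$d), u = res$u)
}

#' Robust score components W_j at each distinct time
#'
#' Lin--Wei score residuals at \eqn{\beta = 0} (Breslow tie convention),
#' aggregated over the subjects exiting (failing or censored) at each distinct
#' time: \eqn{W_j = U_j - \sum_{t_l \le t_j} (d_l / n_l)
#' \sum_{i \in E_j} (z_i - \bar z_{R_l})}. The correction subtracts a weighted
#' average of score contributions at earlier times, making the \eqn{W_j}
#' approximately independent and identically distributed; their sum equals
#' \eqn{\sum_j U_j} exactly.
#'
#' @inheritParams breslow_loglik
#' @return A tibble with columns `time`, `n_fail`, `u`, `w`.
#' @export
robust_components <- function(data, covariate, time = time, event = event) {
  dc <- rs_decomp(dplyr::pull(data, {{ time }}), dplyr::pull(data, {{ event }}))
  res <- sep_core(dc, pull_z(data, {{ covariate }}), need_index = FALSE)
  tibble(time = dc$tj, n_fail = as.integer(dc$d), u = res$u, w = res$w)
}

#' Theoretical maximum of the separability statistic
#'
#' The limiting value of \eqn{|\Delta_0| = |\sum_j U_j|} when the covariate
#' perfectly orders failures: at each failure time the \eqn{d_j} failing
#' subjects are taken to be the members of the risk set with the most extreme
#' covariate values in the direction of the observed effect (the
#' \eqn{\beta \to \infty} limit conditioned on the observed risk sets).
#' Always \eqn{\ge |\Delta_0|}.
#'
#' @inheritParams breslow_loglik
#' @return A length-one positive numeric.
#' @export
delta_max <- function(data, covariate, time = time, event = event) {
  dc <- rs_decomp(dplyr::pull(data, {{ time }}), dplyr::pull(data, {{ event }}))
  sep_core(dc, pull_z(data, {{ covariate }}))$dmax
}

#' Separability index for one covariate
#'
#' Computes \eqn{\Delta_0 = \sum_j W_j = \sum_j U_j} (the robust score at
#' \eqn{\beta = 0}), its theoretical maximum \eqn{D_{max}}, and the index
#' \eqn{|\Delta_0| / D_{max} \in [0, 1]}, interpreted as the percentage of
#' separability over time between the subjects observed to fail and those at
#' risk. The associated robust score statistic
#' \eqn{S_0 = (\sum_j W_j)^2 / \sum_j W_j^2} is referred to an asymptotic
#' chi-square distribution with 1 degree of freedom. The direction of the
#' effect (hazard ratio above or below 1) is reported separately from the
#' index.
#'
#' @inheritParams breslow_loglik
#' @return A one-row tibble with columns `delta0`, `dmax`, `index`,
#'   `direction` (`"HR>1"` or `"HR<1"`), `score_stat`, `p_value`.
#' @examples
#' d <- simulate_survival(200, hr = 3, seed = 1)
#' separability_index(d, z)
#' @export
separability_index <- function(data, covariate, time = time, event = event) {
  dc <- rs_decomp(dplyr::pull(data, {{ time }}), dplyr::pull(data, {{ event }}))
  res <- sep_core(dc, pull_z(data, {{ covariate }}))
  tibble(
    delta0 = res$delta0,
    dmax = res$dmax,
    index = res$index,
    direction = if (res$direction > 0) "HR>1" else "HR<1",
    score_stat = res$score_stat,
    p_value = res$p_value
  )
}
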