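# Risk-set decomposition and the Breslow partial likelihood for a single
# covariate. All internal numerics work on a lightweight decomposition list
# computed once per (time, event) pair and shared across covariates/genes.

#' Reverse cumulative sum
#' @noRd
revcumsum <- function(x) {
  rev(cumsum(rev(x)))
}

#' Internal risk-set decomposition
#'
#' Subjects are sorted by observed time; the risk set at a distinct time t_j
#' is the suffix of subjects with time >= t_j (subjects censored at t_j are
#' kept at risk: censoring-after-failure convention).
#'
#' @return list with ord (permutation sorting subjects by time), tj (distinct
#'   times), first (start index of each distinct-time block in sorted order),
#'   block (distinct-time id per sorted subject), d/n/e (failures, at-risk,
#'   exits per distinct time), status (sorted event indicator), k (distinct
#'   failure times), n_events (total failures).
#' @noRd
rs_decomp <- function(time, event) {
  if (length(time) != length(event)) {
    abort("`time` and `event` must have the same length.")
  }
  if (anyNA(time) || anyNA(event)) {
    abort("`time` and `event` must not contain missing values.")
  }
  if (any(time < 0)) {
    abort("`time` must be nonnegative.")
  }
  if (!all(event %in% c(0, 1))) {
    bad <- unique(event[!event %in% c(0, 1)])
    abort(paste0(
      "`event` must be coded 0/1; offending values: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (sum(event) < 1) {
    abort("no failures: at least one event is required.")
  }
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  first <- which(!duplicated(t_s))
  cnt <- diff(c(first, length(t_s) + 1L))
  N <- length(first)
  block <- rep.int(seq_len(N), cnt)
  d <- as.vector(rowsum(e_s, block))
  list(
    ord = ord, tj = t_s[first], first = first, block = block,
    d = d, n = length(t_s) - first + 1L, e = cnt,
    status = e_s, N = N, k = sum(d > 0L), n_events = sum(e_s),
    n_subjects = length(t_s)
  )
}

#' Decompose follow-up data into risk sets at each distinct time
#'
#' Computes, for every distinct observed time \eqn{t_j} (failure or censoring),
#' the set of subjects failing at \eqn{t_j} (\eqn{D_j}), the risk set
#' (\eqn{R_j}, subjects with observed time \eqn{\ge t_j}), the subjects
#' exiting at \eqn{t_j} (\eqn{E_j}, failing or censored), and the risk set
#' without the failures (\eqn{R^*_j}), together with their cardinalities
#' \eqn{d_j}, \eqn{n_j}, \eqn{e_j}. Ties between failures and censorings at
#' the same time are allowed; censored subjects remain in the risk set at
#' their exit time.
#'
#' @param data A data frame with one row per subject.
#' @param time,event Columns of `data` holding the nonnegative follow-up time
#'   and the 0/1 event indicator (1 = failure). Defaults to columns named
#'   `time` and `event`.
#' @return A tibble of class `"risk_sets"` with one row per distinct time and
#'   columns `time`, `n_risk`, `n_fail`, `n_exit`, `death` (any failure at
#'   this time) and list-columns `at_risk`, `failing`, `exiting`,
#'   `at_risk_after` holding subject row indices of `data`. The internal
#'   decomposition is attached as attribute `"decomp"`.
#' @examples
#' d <- tibble::tibble(time = c(2, 1, 1, 3), event = c(1, 1, 0, 0))
#' rs <- risk_sets(d)
#' rs$n_risk
#' @export
risk_sets <- function(data, time = time, event = event) {
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  dc <- rs_decomp(tm, ev)
  ids <- dc$ord
  n_tot <- dc$n_subjects
  at_risk <- lapply(dc$first, function(f) sort(ids[f:n_tot]))
  exiting <- lapply(seq_len(dc$N), function(j) {
    sort(ids[dc$block == j])
  })
  failing <- lapply(seq_len(dc$N), function(j) {
    sort(ids[dc$block == j][dc$status[dc$block == j] == 1])
  })
  out <- tibble(
    time = dc$tj,
    n_risk = dc$n,
    n_fail = as.integer(dc$d),
    n_exit = as.integer(dc$e),
    death = dc$d > 0,
    at_risk = at_risk,
    failing = failing,
    exiting = exiting,
    at_risk_after = purrr::map2(at_risk, failing, setdiff)
  )
  attr(out, "decomp") <- dc
  class(out) <- c("risk_sets", class(out))
  out
}

#' Risk set at one time excluding the subjects exiting at a later time
#'
#' Returns \eqn{R^*(t_{l(-j)})}: the risk set at the l-th distinct time with
#' the subjects failing or censored at the j-th distinct time removed
#' (requires `l < j`).
#'
#' @param rs A `"risk_sets"` object.
#' @param l,j Indices of distinct times, `l < j`.
#' @return Sorted integer vector of subject row indices.
#' @export
risk_set_excluding <- function(rs, l, j) {
  stopifnot(inherits(rs, "risk_sets"), l < j, j <= nrow(rs))
  setdiff(rs$at_risk[[l]], rs$exiting[[j]])
}

# suffix log-sum-exp and moment sums used by likelihood/score/information;
# returns per-distinct-time values (length N)
bl_suffix <- function(dc, zs, beta) {
  a <- beta * zs
  m <- max(a)
  ea <- exp(a - m)
  s0 <- revcumsum(ea)[dc$first]
  s1 <- revcumsum(zs * ea)[dc$first]
  s2 <- revcumsum(zs * zs * ea)[dc$first]
  list(log_s0 = m + log(s0), r1 = s1 / s0, r2 = s2 / s0)
}

bl_loglik <- function(dc, zs, beta) {
  sf <- bl_suffix(dc, zs, beta)
  sum_d_z <- as.vector(rowsum(zs * dc$status, dc$block))
  sum(beta * sum_d_z - dc$d * sf$log_s0)
}

bl_score <- function(dc, zs, beta) {
  sf <- bl_suffix(dc, zs, beta)
  sum_d_z <- as.vector(rowsum(zs * dc$status, dc$block))
  sum(sum_d_z - dc$d * sf$r1)
}

bl_info <- function(dc, zs, beta) {
  sf <- bl_suffix(dc, zs, beta)
  sum(dc$d * (sf$r2 - sf$r1^2))
}

pull_z <- function(data, covariate) {
  z <- dplyr::pull(data, {{ covariate }})
  if (anyNA(z)) abort("the covariate must not contain missing values.")
  z
}

#' Breslow partial log-likelihood for one covariate
#'
#' \eqn{\ell(\beta) = \sum_j [\sum_{i \in D_j} \beta z_i -
#' d_j \log \sum_{i \in R_j} e^{\beta z_i}]}, summing over distinct times with
#' the Peto--Breslow handling of tied failures. The inner log-sum is computed
#' with a max-shift for numerical stability.
#'
#' @inheritParams risk_sets
#' @param covariate Column of `data` holding the covariate.
#' @param beta Regression coefficient (finite scalar).
#' @return A length-one numeric.
#' @export
breslow_loglik <- function(data, covariate, beta = 0, time = time,
                           event = event) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  dc <- rs_decomp(dplyr::pull(data, {{ time }}), dplyr::pull(data, {{ event }}))
  bl_loglik(dc, pull_z(data, {{ covariate }})[dc$ord], beta)
}

#' Score (first derivative) of the Breslow partial log-likelihood
#'
#' \eqn{U(\beta) = \sum_j [\sum_{i \in D_j} z_i - d_j
#' \sum_{R_j} z e^{\beta z} / \sum_{R_j} e^{\beta z}]}.
#'
#' @inheritParams breslow_loglik
#' @return A length-one numeric.
#' @export
breslow_score <- function(data, covariate, beta = 0, time = time,
                          event = event) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  dc <- rs_decomp(dplyr::pull(data, {{ time }}), dplyr::pull(data, {{ event }}))
  bl_score(dc, pull_z(data, {{ covariate }})[dc$ord], beta)
}

# Newton-Raphson on the Breslow partial likelihood; internal engine shared by
# cox_fit() and the per-gene screen.
fit_cox_core <- function(dc, zs, tol = 1e-8, max_iter = 50L, beta_cap = 20) {
  j0 <- match(TRUE, dc$d > 0L)
  z_risk <- zs[dc$first[j0]:dc$n_subjects]
  if (diff(range(z_risk)) == 0) {
    abort("constant covariate: Cox fit is not identifiable.")
  }
  ll0 <- bl_loglik(dc, zs, 0)
  beta <- 0
  ll <- ll0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    u <- bl_score(dc, zs, beta)
    if (abs(u) < tol) {
      converged <- TRUE
      break
    }
    info <- bl_info(dc, zs, beta)
    step <- u / info
    if (!is.finite(step)) break
    beta_new <- max(-beta_cap, min(beta_cap, beta + step))
    ll_new <- bl_loglik(dc, zs, beta_new)
    halvings <- 0L
    while (ll_new < ll - 1e-12 && halvings < 25L) {
      beta_new <- (beta + beta_new) / 2
      ll_new <- bl_loglik(dc, zs, beta_new)
      halvings <- halvings + 1L
    }
    if (abs(beta_new - beta) < 1e-14) {
      beta <- beta_new
      ll <- ll_new
      break
    }
    beta <- beta_new
    ll <- ll_new
  }
  if (!converged) converged <- abs(bl_score(dc, zs, beta)) < tol
  # a diverging estimate (monotone likelihood) ends at or just below the cap
  if (abs(beta) >= 0.95 * beta_cap) converged <- FALSE
  list(
    beta = beta, loglik_null = ll0, loglik = ll,
    lr = max(0, 2 * (ll - ll0)), info = bl_info(dc, zs, beta),
    converged = converged
  )
}

#' Fit a one-covariate Cox model by Newton--Raphson (Breslow ties)
#'
#' Maximizes the Breslow partial likelihood from \eqn{\beta = 0} with
#' step-halving on likelihood decrease. A monotone likelihood (covariate
#' separating failures completely) is reported as non-converged with
#' \eqn{\hat\beta} capped at `beta_cap`.
#'
#' @inheritParams breslow_loglik
#' @param tol Convergence tolerance on the absolute score.
#' @param max_iter Maximum Newton iterations.
#' @param beta_cap Bound on \eqn{|\hat\beta|}.
#' @return An object of class `"sep_coxfit"`: a list with `beta`,
#'   `loglik_null` (\eqn{\ell(0)}), `loglik` (\eqn{\ell(\hat\beta)}),
#'   `lr_statistic`, `n`, `n_events`, `k_failure_times`, `converged`, and the
#'   internal decomposition. Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' d <- simulate_survival(100, hr = 2, seed = 1)
#' glance(cox_fit(d, z))
#' @export
cox_fit <- function(data, covariate, time = time, event = event,
                    tol = 1e-8, max_iter = 50L, beta_cap = 20) {
  dc <- rs_decomp(dplyr::pull(data, {{ time }}), dplyr::pull(data, {{ event }}))
  z <- pull_z(data, {{ covariate }})
  fit <- fit_cox_core(dc, z[dc$ord], tol = tol, max_iter = max_iter,
                      beta_cap = beta_cap)
  structure(
    list(
      beta = fit$beta, loglik_null = fit$loglik_null, loglik = fit$loglik,
      lr_statistic = fit$lr, info = fit$info, n = dc$n_subjects,
      n_events = dc$n_events, k_failure_times = dc$k,
      converged = fit$converged, decomp = dc, z_sorted = z[dc$ord]
    ),
    class = "sep_coxfit"
  )
}

#' @export
print.sep_coxfit <- function(x, ...) {
  cat("One-covariate Cox model (Breslow ties)\n")
  cat(sprintf(
    "  n = %d, events = %d, distinct failure times = %d\n",
    x$n, x$n_events, x$k_failure_times
  ))
  cat(sprintf(
    "  beta = %.5f (HR = %.4f), LR = %.4f, converged: %s\n",
    x$beta, exp(x$beta), x$lr_statistic, x$converged
  ))
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `"sep_coxfit"` object.
#' @param ... Unused.
#' @method tidy sep_coxfit
#' @export
tidy.sep_coxfit <- function(x, ...) {
  se <- 1 / sqrt(x$info)
  tibble(
    term = "covariate",
    estimate = x$beta,
    std.error = se,
    statistic = x$beta / se,
    p.value = pchisq((x$beta / se)^2, 1, lower.tail = FALSE)
  )
}

#' @rdname cox_fit
#' @method glance sep_coxfit
#' @export
glance.sep_coxfit <- function(x, ...) {
  tibble(
    logLik_null = x$loglik_null,
    logLik = x$loglik,
    lr_statistic = x$lr_statistic,
    p.value.lr = pchisq(x$lr_statistic, 1, lower.tail = FALSE),
    n = x$n,
    n_events = x$n_events,
    k_failure_times = x$k_failure_times,
    converged = x$converged
  )
}
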