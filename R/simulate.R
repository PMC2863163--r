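# Survival simulation: proportional-hazards and proportional-odds generators,
# variance-matched covariate laws, and censoring mechanisms calibrated to an
# expected overall censoring fraction.

sim_model <- function(model) arg_match0(model, c("ph", "po"))
sim_covariate <- function(covariate) {
  arg_match0(covariate, c("bernoulli", "uniform"))
}
sim_censoring <- function(censoring) {
  arg_match0(censoring, c("none", "uniform", "exponential"))
}

#' Draw a covariate with variance 1/4
#'
#' `"bernoulli"` draws \eqn{Z \in \{0, 1\}} with probability 1/2;
#' `"uniform"` draws \eqn{Z \sim U[0, \sqrt 3]}. Both laws have variance 1/4,
#' so effect sizes \eqn{e^\beta} are comparable across them.
#'
#' @param n Number of subjects.
#' @param covariate `"bernoulli"` or `"uniform"`.
#' @param seed Optional integer seed (the draw is deterministic given it).
#' @return Numeric vector of length `n`.
#' @export
draw_covariate <- function(n, covariate = c("bernoulli", "uniform"),
                           seed = NULL) {
  covariate <- sim_covariate(covariate[1])
  draw <- function() {
    switch(covariate,
      bernoulli = rbinom(n, 1, 0.5),
      uniform = runif(n, 0, sqrt(3))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Draw survival times from a proportional-hazards or proportional-odds model
#'
#' Inverse-transform sampling from \eqn{S(t; z) = \exp(-t e^{\beta z})}
#' (`"ph"`; unit-rate exponential baseline) or
#' \eqn{S(t; z) = (1 + t e^{\beta z})^{-1}} (`"po"`; log-logistic baseline,
#' covariate effect on the hazard wanes with time).
#'
#' @param z Covariate vector.
#' @param beta Regression coefficient (log hazard/odds ratio).
#' @param model `"ph"` or `"po"`.
#' @param seed Optional integer seed.
#' @return Vector of survival times, one per element of `z`.
#' @export
draw_survival <- function(z, beta, model = c("ph", "po"), seed = NULL) {
  stopifnot(is.finite(beta))
  model <- sim_model(model[1])
  draw <- function() {
    u <- runif(length(z))
    switch(model,
      ph = -log(u) * exp(-beta * z),
      po = (1 / u - 1) * exp(-beta * z)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# P(subject with covariate z is censored) under the mechanism, as a function
# of the mechanism parameter. Closed forms where available, numeric otherwise.
censor_prob_given_z <- function(par, z, beta, model, mechanism) {
  lam <- exp(beta * z)
  if (mechanism == "uniform") {
    # C ~ U(0, par): P(C < T | z) = (1/par) * int_0^par S(t; z) dt
    switch(model,
      ph = (1 - exp(-par * lam)) / (par * lam),
      po = log1p(par * lam) / (par * lam)
    )
  } else {
    # C ~ Exp(par): P(C < T | z) = int_0^inf par e^{-par t} S(t; z) dt
    switch(model,
      ph = par / (par + lam),
      po = vapply(lam, function(l) {
        # substitute u = par * t so the exponential weight is O(1)
        integrate(function(u) exp(-u) / (1 + l * u / par),
                  0, Inf, rel.tol = 1e-10)$value
      }, numeric(1))
    )
  }
}

censor_prob_marginal <- function(par, beta, model, mechanism, covariate) {
  if (covariate == "bernoulli") {
    mean(censor_prob_given_z(par, c(0, 1), beta, model, mechanism))
  } else {
    integrate(
      function(z) censor_prob_given_z(par, z, beta, model, mechanism),
      0, sqrt(3), rel.tol = 1e-9
    )$value / sqrt(3)
  }
}

#' Calibrate a censoring mechanism to an expected censoring fraction
#'
#' Finds the parameter of the censoring law -- the upper bound \eqn{r} of a
#' uniform \eqn{U(0, r)} censoring time, or the rate \eqn{\gamma} of an
#' exponential one -- such that the expected overall proportion of censored
#' observations, marginalized over the covariate law, equals `p_c`. Solved by
#' one-dimensional root finding on the (closed-form or numerically
#' integrated) censoring probability.
#'
#' @param p_c Expected overall censoring fraction in `[0, 1)`; `0` returns
#'   `Inf` for the uniform bound and `0` for the exponential rate (no
#'   censoring sentinels).
#' @param mechanism `"uniform"` or `"exponential"`.
#' @param model `"ph"` or `"po"` survival model.
#' @param beta Log hazard/odds ratio used to generate survival times.
#' @param covariate Covariate law, as in [draw_covariate()].
#' @return Length-one numeric parameter.
#' @examples
#' # T ~ Exp(1): P(censored) = (1 - exp(-r)) / r = 0.25 at r ~ 3.92
#' solve_censoring_parameter(0.25)
#' @export
solve_censoring_parameter <- function(p_c,
                                      mechanism = c("uniform", "exponential"),
                                      model = c("ph", "po"), beta = 0,
                                      covariate = c("bernoulli", "uniform")) {
  mechanism <- arg_match0(mechanism[1], c("uniform", "exponential"))
  model <- sim_model(model[1])
  covariate <- sim_covariate(covariate[1])
  stopifnot(is.numeric(p_c), length(p_c) == 1L, p_c >= 0, p_c < 1)
  if (p_c == 0) return(if (mechanism == "uniform") Inf else 0)
  f <- function(par) {
    censor_prob_marginal(par, beta, model, mechanism, covariate) - p_c
  }
  # censoring probability is monotone in the parameter (decreasing in r,
  # increasing in gamma); bracket on a wide log-spaced interval
  lower <- 1e-8
  upper <- 1e8
  root <- tryCatch(
    uniroot(f, c(lower, upper), tol = 1e-10)$root,
    error = function(e) abort(paste0(
      "no censoring parameter in bounds for p_c = ", p_c, ": ",
      conditionMessage(e)
    ))
  )
  root
}

#' Simulate one survival dataset
#'
#' Draws a covariate, survival times from the chosen model, and independent
#' censoring times calibrated so the expected censoring fraction is `p_c`.
#' The observed time is \eqn{\min(T, C)} with event indicator
#' \eqn{1\{T \le C\}}.
#'
#' @param n Number of subjects.
#' @param model `"ph"` or `"po"`.
#' @param hr Effect size \eqn{e^\beta} (hazard ratio for `"ph"`, odds ratio
#'   for `"po"`).
#' @param covariate Covariate law, see [draw_covariate()].
#' @param censoring `"none"`, `"uniform"` or `"exponential"`.
#' @param p_c Expected censoring fraction (ignored when `censoring = "none"`).
#' @param censor_par Optional pre-solved censoring parameter; when `NULL` it
#'   is calibrated with [solve_censoring_parameter()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `time`, `event`, `z`.
#' @examples
#' simulate_survival(5, hr = 2, seed = 1)
#' @export
simulate_survival <- function(n, model = c("ph", "po"), hr = 1,
                              covariate = c("bernoulli", "uniform"),
                              censoring = c("none", "uniform", "exponential"),
                              p_c = 0, censor_par = NULL, seed = NULL) {
  stopifnot(n >= 2, hr > 0, p_c >= 0, p_c < 1)
  model <- sim_model(model[1])
  covariate <- sim_covariate(covariate[1])
  censoring <- sim_censoring(censoring[1])
  if (censoring == "none" || p_c == 0) {
    censoring <- "none"
  } else if (is.null(censor_par)) {
    censor_par <- solve_censoring_parameter(
      p_c, mechanism = censoring, model = model, beta = log(hr),
      covariate = covariate
    )
  }
  draw <- function() {
    z <- draw_covariate(n, covariate)
    t_surv <- draw_survival(z, log(hr), model)
    if (censoring == "none") {
      tibble(id = seq_len(n), time = t_surv, event = 1, z = z)
    } else {
      cns <- switch(censoring,
        uniform = runif(n, 0, censor_par),
        exponential = rexp(n, censor_par)
      )
      tibble(
        id = seq_len(n),
        time = pmin(t_surv, cns),
        event = as.numeric(t_surv <= cns),
        z = z
      )
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# all five indices on one dataset; NA comparisons if the fit fails
all_indices_core <- function(dc, z) {
  sep <- sep_core(dc, z)
  cmp <- tryCatch({
    fit <- fit_cox_core(dc, z[dc$ord])
    if (!fit$converged) {
      c(allison = NA_real_, allison_modified = NA_real_,
        nagelkerke = NA_real_, xu_oquigley = NA_real_)
    } else {
      lr <- fit$lr
      allison <- 1 - exp(-lr / dc$n_subjects)
      fitobj <- structure(
        list(beta = fit$beta, converged = TRUE, decomp = dc,
             z_sorted = z[dc$ord], lr_statistic = lr),
        class = "sep_coxfit"
      )
      c(
        allison = allison,
        allison_modified = 1 - exp(-lr / dc$n_events),
        nagelkerke = allison / (1 - exp(2 * fit$loglik_null / dc$n_subjects)),
        xu_oquigley = xu_oquigley_index(fitobj)
      )
    }
  }, error = function(e) {
    c(allison = NA_real_, allison_modified = NA_real_,
      nagelkerke = NA_real_, xu_oquigley = NA_real_)
  })
  c(separability = sep$index, cmp)
}

#' Simulation study comparing the separability index with four competitors
#'
#' For each configuration row, simulates `replicates` datasets, computes the
#' separability index and the four likelihood-based indices on each (paired),
#' and summarizes means, standard errors, and the paired differences
#' \eqn{\delta} = separability minus competitor with 95% confidence
#' intervals.
#'
#' @param configs A data frame with columns among `model`, `hr`, `covariate`,
#'   `censoring`, `p_c`, `n` (missing columns take the defaults of
#'   [simulate_survival()]); one row per configuration.
#' @param replicates Number of replicate datasets per configuration.
#' @param seed Optional master seed; replicate streams are drawn sequentially
#'   from it.
#' @return A tibble of class `"sep_study"`: one row per configuration and
#'   index with columns `index_name`, `mean`, `se`, `n_used`, and for the
#'   competitors the paired difference summary `delta_mean`, `delta_lo`,
#'   `delta_hi`.
#' @examples
#' cfg <- tidyr::crossing(model = "ph", hr = c(1, 2), n = 50)
#' run_index_study(cfg, replicates = 10, seed = 1)
#' @export
run_index_study <- function(configs, replicates = 1000, seed = NULL) {
  stopifnot(is.data.frame(configs), nrow(configs) >= 1, replicates >= 2)
  defaults <- list(
    model = "ph", hr = 1, covariate = "bernoulli",
    censoring = "none", p_c = 0, n = 100
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(configs)) configs[[nm]] <- defaults[[nm]]
  }
  run <- function() {
    purrr::map_dfr(seq_len(nrow(configs)), function(r) {
      cf <- configs[r, ]
      censoring <- if (cf$p_c == 0) "none" else cf$censoring
      cpar <- if (censoring == "none") NULL else {
        solve_censoring_parameter(
          cf$p_c, mechanism = censoring, model = cf$model,
          beta = log(cf$hr), covariate = cf$covariate
        )
      }
      vals <- vapply(seq_len(replicates), function(i) {
        d <- simulate_survival(
          cf$n, model = cf$model, hr = cf$hr, covariate = cf$covariate,
          censoring = censoring, p_c = cf$p_c, censor_par = cpar
        )
        all_indices_core(rs_decomp(d$time, d$event), d$z)
      }, numeric(5))
      sep <- vals["separability", ]
      purrr::map_dfr(rownames(vals), function(nm) {
        x <- vals[nm, ]
        ok <- !is.na(x)
        out <- dplyr::bind_cols(
          cf,
          tibble(
            index_name = nm,
            mean = mean(x[ok]),
            se = sd(x[ok]) / sqrt(sum(ok)),
            n_used = sum(ok)
          )
        )
        if (nm != "separability") {
          dlt <- sep[ok] - x[ok]
          dm <- mean(dlt)
          dse <- sd(dlt) / sqrt(length(dlt))
          out$delta_mean <- dm
          out$delta_lo <- dm - qnorm(0.975) * dse
          out$delta_hi <- dm + qnorm(0.975) * dse
        } else {
          out$delta_mean <- NA_real_
          out$delta_lo <- NA_real_
          out$delta_hi <- NA_real_
        }
        out
      })
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("sep_study", class(out))
  out
}
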