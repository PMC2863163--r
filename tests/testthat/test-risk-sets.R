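toy <- tibble::tibble(
  time = c(2, 1, 1, 3),
  event = c(1, 1, 0, 0),
  z = c(0, 1, 0, 1)
)

test_that("risk-set decomposition matches hand enumeration on tied data", {
  rs <- risk_sets(toy)
  expect_equal(nrow(rs), 3L)
  expect_equal(rs$time, c(1, 2, 3))
  expect_equal(attr(rs, "decomp")$k, 2L)
  # t = 1
  expect_equal(rs$at_risk[[1]], 1:4)
  expect_equal(rs$failing[[1]], 2L)
  expect_equal(rs$exiting[[1]], c(2L, 3L))
  expect_equal(rs$at_risk_after[[1]], c(1L, 3L, 4L))
  expect_equal(rs$n_fail[1], 1L)
  expect_equal(rs$n_risk[1], 4L)
  expect_equal(rs$n_exit[1], 2L)
  # t = 2 and t = 3
  expect_equal(rs$at_risk[[2]], c(1L, 4L))
  expect_equal(rs$failing[[2]], 1L)
  expect_equal(rs$at_risk[[3]], 4L)
  expect_equal(rs$failing[[3]], integer(0))
  expect_false(rs$death[3])
  # invariants: exits partition subjects, risk sets contain failures
  expect_equal(sum(rs$n_exit), nrow(toy))
  expect_true(all(mapply(function(r, d) all(d %in% r),
                         rs$at_risk, rs$failing)))
  # pairwise exclusion set R*(t_1(-2)): risk set at t1 minus exits at t2
  expect_equal(risk_set_excluding(rs, 1, 2), c(2L, 3L, 4L))
})

test_that("no censoring and no ties gives the identity decomposition", {
  n <- 12
  d <- tibble::tibble(time = sample(seq_len(n)), event = rep(1, n))
  rs <- risk_sets(d)
  expect_equal(nrow(rs), n)
  expect_equal(rs$n_risk, seq(n, 1))
  expect_equal(rs$n_fail, rep(1L, n))
  expect_equal(rs$n_exit, rep(1L, n))
})

test_that("degenerate inputs are rejected", {
  expect_error(risk_sets(tibble::tibble(time = c(1, 2), event = c(0, 0))),
               "no failures")
  expect_error(risk_sets(tibble::tibble(time = c(-1, 2), event = c(1, 1))),
               "nonnegative")
  expect_error(risk_sets(tibble::tibble(time = c(1, 2), event = c(1, 2))),
               "0/1")
})

test_that("Breslow log partial likelihood matches closed form and oracle", {
  expect_equal(breslow_loglik(toy, z, 0), -(log(4) + log(2)))
  # closed form at beta = 0: -sum d_j log n_j
  withr::with_seed(5, {
    for (i in 1:20) {
      d <- random_dataset()
      dc <- attr(risk_sets(d), "decomp")
      expect_equal(breslow_loglik(d, z, 0), -sum(dc$d * log(dc$n)))
      for (b in c(-1.3, 0.4, 2)) {
        expect_equal(breslow_loglik(d, z, b),
                     oracle_loglik(d$time, d$event, d$z, b))
        expect_equal(breslow_score(d, z, b),
                     oracle_score(d$time, d$event, d$z, b))
      }
    }
  })
})

test_that("constant covariate gives flat likelihood shape and zero score", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1), z = 2)
  for (b in c(-1, 0, 0.5, 3)) {
    expect_equal(breslow_score(d, z, b), 0)
    # l(b) = l(0) + b*c*(#failures) - sum_j d_j * b * c
    expect_equal(breslow_loglik(d, z, b), breslow_loglik(d, z, 0))
  }
})

test_that("score equals the central finite difference of the likelihood", {
  withr::with_seed(8, {
    for (i in 1:10) {
      d <- random_dataset(25)
      for (b in c(-0.7, 0, 1.2)) {
        h <- 1e-5
        fd <- (breslow_loglik(d, z, b + h) -
                 breslow_loglik(d, z, b - h)) / (2 * h)
        expect_equal(breslow_score(d, z, b), fd, tolerance = 1e-6)
      }
    }
  })
})

test_that("log partial likelihood is concave in beta", {
  withr::with_seed(9, {
    for (i in 1:10) {
      d <- random_dataset(25)
      grid <- seq(-3, 3, length.out = 31)
      ll <- vapply(grid, function(b) breslow_loglik(d, z, b), numeric(1))
      expect_true(all(diff(diff(ll)) <= 1e-8))
    }
  })
})

test_that("Newton Cox fit agrees with a bounded 1-D optimizer and coxph", {
  skip_if_not_installed("survival")
  withr::with_seed(10, {
    for (i in 1:10) {
      d <- random_dataset(40)
      fit <- cox_fit(d, z)
      expect_true(fit$converged)
      opt <- optimize(function(b) breslow_loglik(d, z, b), c(-10, 10),
                      maximum = TRUE, tol = 1e-9)
      expect_equal(fit$beta, opt$maximum, tolerance = 1e-5)
      ref <- survival::coxph(survival::Surv(time, event) ~ z, data = d,
                             ties = "breslow")
      expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
      expect_equal(fit$lr_statistic,
                   unname(2 * diff(ref$loglik)), tolerance = 1e-6)
    }
  })
})

test_that("fit on symmetric two-group data returns beta = 0, LR = 0", {
  d <- tibble::tibble(
    time = rep(c(1, 2, 3), 2), event = rep(1, 6), z = rep(c(0, 1), each = 3)
  )
  fit <- cox_fit(d, z)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$lr_statistic, 0, tolerance = 1e-10)
})

test_that("Cox fit recovers the simulation effect at large n", {
  betas <- vapply(1:20, function(i) {
    d <- simulate_survival(1000, hr = 2, seed = 100 + i)
    cox_fit(d, z)$beta
  }, numeric(1))
  expect_equal(mean(betas), log(2), tolerance = 0.05)
})

test_that("monotone likelihood is flagged non-converged at the cap", {
  # covariate perfectly separates early failures from later ones
  d <- tibble::tibble(
    time = c(1, 2, 3, 4), event = c(1, 1, 1, 1), z = c(1, 1, 0, 0)
  )
  fit <- cox_fit(d, z)
  expect_false(fit$converged)
  expect_gte(abs(fit$beta), 19)
  expect_lte(abs(fit$beta), 20)
  expect_error(cox_fit(dplyr::mutate(d, z = 1), z), "constant")
  expect_true(all(is.na(likelihood_ratio_indices(fit))))
  expect_true(is.na(xu_oquigley_index(fit)))
})

test_that("tidy and glance return well-formed one-row tibbles", {
  fit <- cox_fit(simulate_survival(80, hr = 2, seed = 3), z)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(gl$n, 80)
  expect_true(gl$lr_statistic >= 0)
  expect_true(gl$logLik >= gl$logLik_null)
})
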