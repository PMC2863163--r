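toy <- tibble::tibble(
  time = c(2, 1, 1, 3),
  event = c(1, 1, 0, 0),
  z = c(0, 1, 0, 1)
)

test_that("null score components match hand computation on the toy data", {
  u <- score_components(toy, z)
  expect_equal(u$u, c(0.5, -0.5, 0))
  expect_equal(sum(u$u), breslow_score(toy, z, 0))
})

test_that("U_j is the scaled mean difference between failing and surviving", {
  withr::with_seed(21, {
    for (i in 1:15) {
      d <- random_dataset(35)
      rs <- risk_sets(d)
      u <- score_components(d, z)$u
      for (j in seq_len(nrow(rs))) {
        dj <- rs$n_fail[j]
        nj <- rs$n_risk[j]
        expected <- if (dj == 0 || dj == nj) {
          if (dj == 0) 0 else sum(d$z[rs$failing[[j]]]) -
            dj * mean(d$z[rs$at_risk[[j]]])
        } else {
          dj * (nj - dj) / nj *
            (mean(d$z[rs$failing[[j]]]) - mean(d$z[rs$at_risk_after[[j]]]))
        }
        expect_equal(u[j], expected)
      }
    }
  })
})

test_that("robust components sum exactly to the score components", {
  expect_equal(robust_components(toy, z)$w, c(0.5, -0.125, -0.375))
  withr::with_seed(22, {
    for (i in 1:50) {
      d <- random_dataset(40)
      comp <- robust_components(d, z)
      expect_lt(abs(sum(comp$w) - sum(comp$u)),
                1e-10 * max(1, sum(abs(comp$w))))
    }
  })
})

test_that("robust components equal per-subject Lin-Wei residuals without ties", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- 30
      d <- tibble::tibble(
        time = runif(n), event = rbinom(n, 1, 0.7), z = rnorm(n)
      )
      d$event[1] <- 1
      w <- robust_components(d, z)
      resid <- oracle_lin_wei(d$time, d$event, d$z)
      # aggregate residuals by the distinct exit time
      agg <- vapply(w$time, function(t) sum(resid[d$time == t]), numeric(1))
      expect_equal(w$w, agg, tolerance = 1e-12)
    }
  })
})

test_that("constant covariate yields zero components and an index error", {
  d <- tibble::tibble(time = 1:5, event = c(1, 0, 1, 1, 0), z = 3)
  expect_equal(score_components(d, z)$u, rep(0, 5))
  expect_equal(robust_components(d, z)$w, rep(0, 5))
  expect_error(separability_index(d, z), "zero separability")
  expect_error(delta_max(d, z), "zero separability")
})

test_that("delta_max bounds |delta0| and the index lies in [0, 1]", {
  withr::with_seed(24, {
    for (i in 1:200) {
      d <- random_dataset(25)
      res <- separability_index(d, z)
      expect_true(res$dmax >= abs(res$delta0) - 1e-12)
      expect_true(res$index >= 0 && res$index <= 1)
      expect_true(res$p_value >= 0 && res$p_value <= 1)
    }
  })
})

test_that("perfect separation over time attains index 1 exactly", {
  # high group fails first, one per time, and empties exactly as failures
  # occur; low group is censored afterwards
  d <- tibble::tibble(
    time = c(1, 2, 3, 4, 5, 5, 5),
    event = c(1, 1, 1, 1, 0, 0, 0),
    z = c(1, 1, 1, 1, 0, 0, 0)
  )
  res <- separability_index(d, z)
  expect_equal(res$delta0, res$dmax)
  expect_equal(res$index, 1)
  expect_equal(res$direction, "HR>1")
})

test_that("index is invariant to location-scale changes of the covariate", {
  withr::with_seed(25, {
    d <- random_dataset(40)
    base <- separability_index(d, z)
    shifted <- separability_index(dplyr::mutate(d, z = 5 - 3 * z), z)
    expect_equal(shifted$index, base$index, tolerance = 1e-12)
    expect_true(shifted$direction != base$direction)
  })
})

test_that("large effects drive the index toward 1", {
  idx <- vapply(1:15, function(i) {
    d <- simulate_survival(200, hr = 50, seed = 300 + i)
    separability_index(d, z)$index
  }, numeric(1))
  expect_gt(mean(idx), 0.8)
})

test_that("direction tracks the sign of the fitted hazard ratio", {
  withr::with_seed(26, {
    for (hr in c(0.3, 3)) {
      d <- simulate_survival(300, hr = hr)
      res <- separability_index(d, z)
      fit <- cox_fit(d, z)
      expect_equal(res$direction, if (fit$beta > 0) "HR>1" else "HR<1")
    }
  })
})
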