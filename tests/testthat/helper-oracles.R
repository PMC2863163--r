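# Independent brute-force oracles built directly from explicit subject sets.
# These deliberately avoid the package's suffix-sum implementation paths.

# explicit risk/death sets per distinct time
oracle_sets <- function(time, event) {
  tj <- sort(unique(time))
  lapply(tj, function(t) {
    list(
      t = t,
      risk = which(time >= t),
      death = which(time == t & event == 1),
      exit = which(time == t)
    )
  })
}

# Breslow partial log-likelihood by direct summation over explicit sets
oracle_loglik <- function(time, event, z, beta) {
  sum(vapply(oracle_sets(time, event), function(s) {
    d <- length(s$death)
    if (d == 0) return(0)
    sum(beta * z[s$death]) - d * log(sum(exp(beta * z[s$risk])))
  }, numeric(1)))
}

# score by direct summation
oracle_score <- function(time, event, z, beta) {
  sum(vapply(oracle_sets(time, event), function(s) {
    d <- length(s$death)
    if (d == 0) return(0)
    w <- exp(beta * z[s$risk])
    sum(z[s$death]) - d * sum(z[s$risk] * w) / sum(w)
  }, numeric(1)))
}

# per-subject Lin-Wei score residuals at beta = 0 (Breslow ties), the
# aggregation target of robust_components()
oracle_lin_wei <- function(time, event, z) {
  sets <- oracle_sets(time, event)
  vapply(seq_along(time), function(i) {
    ri <- 0
    for (s in sets) {
      if (s$t > time[i]) break
      zbar <- mean(z[s$risk])
      dj <- length(s$death)
      nj <- length(s$risk)
      if (time[i] == s$t && event[i] == 1) ri <- ri + (z[i] - zbar)
      if (dj > 0) ri <- ri - dj / nj * (z[i] - zbar)
    }
    ri
  }, numeric(1))
}

# naive reference quantile normalization (column-sort to row means)
oracle_quantile_normalize <- function(x) {
  ranks <- apply(x, 2, rank, ties.method = "average")
  sorted <- apply(x, 2, sort)
  ref <- rowMeans(sorted)
  apply(ranks, 2, function(r) approx(seq_along(ref), ref, xout = r)$y)
}

# small random censored dataset for property loops
random_dataset <- function(n = 30, p_event = 0.7, tie_prob = 0.3) {
  time <- sample.int(ceiling(n * tie_prob * 2) + 3, n, replace = TRUE)
  event <- rbinom(n, 1, p_event)
  if (sum(event) == 0) event[sample.int(n, 1)] <- 1
  tibble::tibble(time = time, event = event, z = rnorm(n))
}
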