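make_long <- function(values_by_study) {
  dplyr::bind_rows(lapply(names(values_by_study), function(s) {
    v <- values_by_study[[s]]
    tibble::tibble(study = s, gene = names(v), index = unname(v))
  }))
}

test_that("meta_select keeps only genes passing in every study", {
  long <- make_long(list(
    a = c(g1 = 0.9, g2 = 0.5, g3 = 0.1),
    b = c(g1 = 0.8, g2 = 0.05, g3 = 0.2)
  ))
  sel <- meta_select(long, index, 0.4)
  expect_equal(sel$gene, "g1")
  # threshold stricter than every value in one study: empty
  expect_equal(nrow(meta_select(long, index, 0.95)), 0L)
  # two identical studies reduce to single-study selection
  long2 <- make_long(list(a = c(g1 = 0.9, g2 = 0.5),
                          b = c(g1 = 0.9, g2 = 0.5)))
  expect_equal(meta_select(long2, index, 0.4)$gene, c("g1", "g2"))
  # q-value style criteria select downwards
  sel_q <- meta_select(dplyr::rename(long, q = index), q, 0.2,
                       select = "less")
  expect_equal(sel_q$gene, "g3")
})

test_that("meta_select reports direction concordance and input errors", {
  long <- make_long(list(a = c(g1 = 0.9, g2 = 0.9),
                         b = c(g1 = 0.8, g2 = 0.8)))
  long$direction <- c("HR>1", "HR<1", "HR>1", "HR>1")
  sel <- meta_select(long, index, 0.5)
  expect_equal(sel$concordant[sel$gene == "g1"], TRUE)
  expect_equal(sel$concordant[sel$gene == "g2"], FALSE)
  disjoint <- make_long(list(a = c(g1 = 1), b = c(g2 = 1)))
  expect_error(meta_select(disjoint, index, 0.5), "no genes")
  one <- make_long(list(a = c(g1 = 1)))
  expect_error(meta_select(one, index, 0.5), "two studies")
})

test_that("independent rankings give intersection ratio near 1", {
  withr::with_seed(71, {
    genes <- sprintf("g%05d", 1:20000)
    long <- make_long(list(
      a = stats::setNames(sample(20000), genes),
      b = stats::setNames(sample(20000), genes)
    ))
    ir <- intersection_ratio(long, index,
                             top_fractions = c(0.05, 0.1, 0.2))
    expect_equal(ir$ratio, rep(1, 3), tolerance = 0.35)
    expect_equal(ir$expected, 20000 * c(0.05, 0.1, 0.2)^2, tolerance = 0.01)
  })
})

test_that("perfectly concordant rankings give ratio 1/p", {
  genes <- sprintf("g%04d", 1:1000)
  v <- stats::setNames(seq(1, 0, length.out = 1000), genes)
  long <- make_long(list(a = v, b = v, c = v))
  ir <- intersection_ratio(long, index, top_fractions = c(0.05, 0.1, 0.2))
  expect_equal(ir$observed, c(50L, 100L, 200L))
  expect_equal(ir$ratio, 1 / c(0.05, 0.1, 0.2)^2)
  expect_true(all(ir$qualifying))
  expect_equal(attr(ir, "chosen"), 0.2)
  # observed counts are monotone as thresholds loosen
  expect_true(all(diff(ir$observed) >= 0))
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 = 1", {
  withr::with_seed(72, {
    p <- c(runif(300)^2, runif(200))
    expect_equal(q_values(p, pi0 = 1), stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)
    # monotone non-decreasing in p after sorting
    q <- q_values(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
    # NA propagation
    p2 <- c(0.01, NA, 0.5)
    expect_true(is.na(q_values(p2)[2]))
  })
})

test_that("pi0 smoother is close to 1 for uniform p-values", {
  withr::with_seed(73, {
    p <- runif(1e4)
    q <- q_values(p)
    bh <- stats::p.adjust(p, "BH")
    # qvalue = pi0 * BH with pi0 estimated near 1
    ratio <- q / bh
    expect_equal(max(ratio), 1, tolerance = 0.1)
    expect_gt(max(ratio), 0.8)
  })
})

test_that("tpf_tnf computes the stated fractions", {
  truth <- tibble::tibble(
    gene = sprintf("g%04d", 1:1000),
    prognostic = 1:1000 <= 100
  )
  expect_equal(tpf_tnf(sprintf("g%04d", 1:100), truth),
               tibble::tibble(tpf = 1, tnf = 1, n_selected = 100L))
  expect_equal(tpf_tnf(sprintf("g%04d", 1:50), truth)$tpf, 0.5)
  expect_equal(tpf_tnf(sprintf("g%04d", 1:50), truth)$tnf, 1)
  empty <- tpf_tnf(character(0), truth)
  expect_equal(c(empty$tpf, empty$tnf), c(0, 1))
})

test_that("operating characteristics are well-formed on a small example", {
  oc <- meta_operating_characteristics(
    iterations = 2, effect = 5, model = "ph", rho = 0.5,
    n = c(60, 30), n_genes = 200, top_fractions = c(0.1, 0.2), seed = 74
  )
  expect_equal(nrow(oc), 10L) # 5 indices x 2 fractions
  expect_true(all(oc$tpf >= 0 & oc$tpf <= 1))
  expect_true(all(oc$tnf >= 0 & oc$tnf <= 1))
  # the separability index recovers prognostic genes well above the
  # chance level (~0.04 for random top-20% lists in two studies)
  expect_gt(oc$tpf[oc$index_name == "index" & oc$top_fraction == 0.2], 0.15)
})
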