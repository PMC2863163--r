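# Cross-study meta-selection: Storey q-values, intersection of ranked lists,
# the observed/expected intersection-ratio curve, and TPF/TNF evaluation.

#' Storey q-values
#'
#' Non-parametric FDR q-values. The proportion of true nulls \eqn{\pi_0} is
#' estimated on a grid of tuning values \eqn{\lambda} as
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))} and
#' smoothed with a cubic smoothing spline evaluated at the largest
#' \eqn{\lambda} (Storey--Tibshirani smoother). With `pi0 = 1` the q-values
#' reduce exactly to Benjamini--Hochberg adjusted p-values. Q-values are
#' monotone non-decreasing in p.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA`s are propagated).
#' @param lambda Grid for the \eqn{\pi_0} smoother.
#' @param pi0 Optional fixed \eqn{\pi_0}, bypassing estimation.
#' @return Numeric vector of q-values, same length as `p`.
#' @export
q_values <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0) return(p)
  if (any(pv < 0 | pv > 1)) abort("p-values must lie in [0, 1].")
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < 100 || max(pv) < max(lambda)) {
      # too few p-values (or none in the tail) for a stable smoother
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(pv)
  q_sorted <- pi0 * m * pv[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- rep(NA_real_, length(p))
  q[ok][o] <- q_sorted
  q
}

check_meta_input <- function(data, value_col) {
  req <- c("study", "gene", value_col)
  if (!all(req %in% names(data))) {
    abort(paste0(
      "`data` must have columns study, gene and `", value_col, "`."
    ))
  }
  universes <- split(data$gene, data$study)
  if (length(universes) < 2) {
    abort("at least two studies are required.")
  }
  shared <- Reduce(intersect, universes)
  if (length(shared) == 0) abort("studies share no genes.")
  invisible(shared)
}

#' Select genes passing a criterion threshold in every study
#'
#' Given per-study, per-gene criterion values in long format, returns the
#' genes whose criterion passes the threshold in all studies
#' (intersection-based meta-selection). For index-type criteria larger is
#' better (`select = "greater"`, gene kept when value >= threshold); for
#' p/q-value criteria use `select = "less"`.
#'
#' @param data Long data frame with columns `study`, `gene`, the criterion
#'   column, and optionally `direction` (per-study effect direction,
#'   reported as concordance).
#' @param criterion Column of `data` holding the selection criterion.
#' @param threshold Numeric threshold.
#' @param select `"greater"` (keep value >= threshold) or `"less"`
#'   (value <= threshold).
#' @return A tibble with one row per selected gene: `gene`, `n_studies`,
#'   `min_value`, `max_value`, and `concordant` when a `direction` column is
#'   present.
#' @export
meta_select <- function(data, criterion, threshold,
                        select = c("greater", "less")) {
  select <- arg_match0(select[1], c("greater", "less"))
  value_col <- as_name(enquo(criterion))
  check_meta_input(data, value_col)
  total_studies <- length(unique(data$study))
  val <- data[[value_col]]
  pass <- !is.na(val) & if (select == "greater") val >= threshold else
    val <= threshold
  out <- data %>%
    dplyr::mutate(.pass = pass) %>%
    group_by(.data$gene) %>%
    summarise(
      n_studies = dplyr::n(),
      all_pass = all(.data$.pass) && dplyr::n() == .env$total_studies,
      min_value = min({{ criterion }}),
      max_value = max({{ criterion }}),
      concordant = if ("direction" %in% names(data)) {
        length(unique(.data$direction)) == 1L
      } else NA,
      .groups = "drop"
    ) %>%
    filter(.data$all_pass) %>%
    select(-"all_pass") %>%
    arrange(.data$gene)
  out
}

#' Observed/expected intersection-ratio curve across studies
#'
#' For each top fraction \eqn{t} of a grid, selects the top \eqn{t} of genes
#' in every study by the criterion (quantile thresholds, so grids are
#' comparable across studies), counts the genes common to all studies
#' \eqn{O(t)}, and compares with the count expected under independence of
#' the rankings, \eqn{E(t) = G \prod_k |S_k(t)|/G}. Thresholds whose ratio
#' \eqn{O/E} exceeds 2 indicate cross-study concordance; the chosen
#' threshold is the loosest qualifying one.
#'
#' @inheritParams meta_select
#' @param top_fractions Grid of top fractions (defaults to 40 points from
#'   0.5% to 20%).
#' @param ratio_min Minimal ratio for a qualifying threshold.
#' @return A tibble of class `"intersection_ratio"`: one row per grid point
#'   with `top_fraction`, `threshold` (loosest per-study criterion value
#'   among selected genes), `observed`, `expected`, `ratio` (`NA` when
#'   `expected` is 0), and `qualifying`. The loosest qualifying fraction is
#'   attached as attribute `"chosen"` (`NA` if none qualifies).
#' @export
intersection_ratio <- function(data, criterion,
                               top_fractions = seq(0.005, 0.2,
                                                   length.out = 40),
                               select = c("greater", "less"),
                               ratio_min = 2) {
  select <- arg_match0(select[1], c("greater", "less"))
  value_col <- as_name(enquo(criterion))
  shared <- check_meta_input(data, value_col)
  if (length(top_fractions) == 0) abort("`top_fractions` must be non-empty.")
  data <- data[data$gene %in% shared & !is.na(data[[value_col]]), ]
  studies <- split(data, data$study)
  big_g <- length(shared)
  # per study: genes ranked best-first with stable gene-id tie-break
  ranked <- lapply(studies, function(s) {
    v <- s[[value_col]]
    o <- if (select == "greater") order(-v, s$gene) else order(v, s$gene)
    s$gene[o]
  })
  rows <- purrr::map_dfr(top_fractions, function(f) {
    n_top <- max(1L, min(big_g, ceiling(f * big_g)))
    tops <- lapply(ranked, head, n_top)
    obs <- length(Reduce(intersect, tops))
    expd <- big_g * prod(vapply(tops, length, integer(1)) / big_g)
    thr <- if (select == "greater") {
      min(vapply(seq_along(ranked), function(k) {
        studies[[k]][[value_col]][match(tops[[k]][n_top],
                                        studies[[k]]$gene)]
      }, numeric(1)))
    } else {
      max(vapply(seq_along(ranked), function(k) {
        studies[[k]][[value_col]][match(tops[[k]][n_top],
                                        studies[[k]]$gene)]
      }, numeric(1)))
    }
    tibble(
      top_fraction = f, threshold = thr, observed = obs, expected = expd,
      ratio = if (expd > 0) obs / expd else NA_real_
    )
  })
  rows$qualifying <- !is.na(rows$ratio) & rows$ratio > ratio_min
  chosen <- if (any(rows$qualifying)) {
    max(rows$top_fraction[rows$qualifying])
  } else {
    NA_real_
  }
  attr(rows, "chosen") <- chosen
  attr(rows, "ratio_min") <- ratio_min
  class(rows) <- c("intersection_ratio", class(rows))
  rows
}

#' True-positive and true-negative fractions of a selection
#'
#' TPF = selected truly-prognostic genes / all truly-prognostic genes;
#' TNF = unselected non-prognostic genes / all non-prognostic genes.
#'
#' @param selected Character vector of selected gene ids.
#' @param truth Data frame with columns `gene` and logical `prognostic`
#'   (as returned in [simulate_meta_example()]`$truth`).
#' @return A one-row tibble with columns `tpf`, `tnf`, `n_selected`.
#' @examples
#' truth <- tibble::tibble(gene = letters[1:4],
#'                         prognostic = c(TRUE, TRUE, FALSE, FALSE))
#' tpf_tnf(c("a", "c"), truth)
#' @export
tpf_tnf <- function(selected, truth) {
  stopifnot(all(c("gene", "prognostic") %in% names(truth)))
  pos <- truth$gene[truth$prognostic]
  neg <- truth$gene[!truth$prognostic]
  tibble(
    tpf = if (length(pos)) length(intersect(selected, pos)) / length(pos)
          else NA_real_,
    tnf = if (length(neg)) length(setdiff(neg, selected)) / length(neg)
          else NA_real_,
    n_selected = length(selected)
  )
}

#' Operating characteristics of the five indices in meta-selection
#'
#' Repeatedly simulates the two-study example, screens both studies with the
#' separability index and the four comparison indices, selects at matched
#' top-fraction thresholds the genes in the intersection of the per-study
#' top lists, and averages TPF/TNF against the known truth over iterations.
#'
#' @param iterations Number of simulated two-study examples.
#' @param top_fractions Grid of top fractions at which selections are made.
#' @inheritParams simulate_meta_example
#' @return A tibble with one row per (index, top fraction): `model`,
#'   `effect`, `rho`, `index_name`, `top_fraction`, `tpf`, `tnf`
#'   (iteration means).
#' @export
meta_operating_characteristics <- function(iterations = 100, effect = 5,
                                           model = c("ph", "po"), rho = 0.5,
                                           n = c(150, 50), n_genes = 1000,
                                           p_c = 0.3,
                                           top_fractions = seq(0.05, 0.2,
                                                               by = 0.05),
                                           seed = NULL) {
  model <- sim_model(model[1])
  index_cols <- c("index", "allison", "allison_modified", "nagelkerke",
                  "xu_oquigley")
  run <- function() {
    acc <- array(
      0, dim = c(length(index_cols), length(top_fractions), 2),
      dimnames = list(index_cols, NULL, c("tpf", "tnf"))
    )
    for (it in seq_len(iterations)) {
      ex <- simulate_meta_example(
        effect = effect, model = model, rho = rho, n = n,
        n_genes = n_genes, p_c = p_c
      )
      screens <- lapply(ex$studies, function(s) {
        separability_screen(s$expression, s$survival,
                            with_comparisons = TRUE, add_q_values = FALSE)
      })
      for (ic in index_cols) {
        ranked <- lapply(screens, function(s) {
          v <- s[[ic]]
          keep <- !is.na(v)
          s$gene[keep][order(-v[keep], s$gene[keep])]
        })
        for (fi in seq_along(top_fractions)) {
          n_top <- max(1L, ceiling(top_fractions[fi] * n_genes))
          sel <- Reduce(intersect, lapply(ranked, head, n_top))
          perf <- tpf_tnf(sel, ex$truth)
          acc[ic, fi, "tpf"] <- acc[ic, fi, "tpf"] + perf$tpf
          acc[ic, fi, "tnf"] <- acc[ic, fi, "tnf"] + perf$tnf
        }
      }
    }
    acc <- acc / iterations
    tidyr::crossing(
      index_name = index_cols, top_fraction = top_fractions
    ) %>%
      mutate(
        model = model, effect = effect, rho = rho,
        tpf = purrr::map2_dbl(.data$index_name, .data$top_fraction,
          ~ acc[.x, match(.y, top_fractions), "tpf"]),
        tnf = purrr::map2_dbl(.data$index_name, .data$top_fraction,
          ~ acc[.x, match(.y, top_fractions), "tnf"])
      ) %>%
      select("model", "effect", "rho", "index_name", "top_fraction",
             "tpf", "tnf")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
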