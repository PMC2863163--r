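# ggplot2 displays for study summaries, the intersection-ratio curve and
# meta-selection operating characteristics.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_ribbon
#'   labs facet_wrap theme_minimal
NULL

#' Plot an index-comparison study
#'
#' Mean index value (with +/- 2 SE ribbons) against the effect size, one
#' line per index, faceted by censoring fraction when several are present.
#'
#' @param object A [run_index_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sep_study
#' @export
autoplot.sep_study <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$hr, y = .data$mean,
                          colour = .data$index_name)) +
    geom_ribbon(
      aes(ymin = .data$mean - 2 * .data$se,
          ymax = .data$mean + 2 * .data$se,
          fill = .data$index_name),
      alpha = 0.15, colour = NA
    ) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "effect size e^beta", y = "mean index", colour = "index",
         fill = "index") +
    theme_minimal()
  if (length(unique(object$p_c)) > 1) {
    p <- p + facet_wrap(~p_c, labeller = ggplot2::label_both)
  }
  p
}

#' Plot an intersection-ratio curve
#'
#' Observed/expected common-gene ratio against the top fraction, with the
#' qualifying-ratio reference line and the chosen threshold highlighted.
#'
#' @param object An [intersection_ratio()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot intersection_ratio
#' @export
autoplot.intersection_ratio <- function(object, ...) {
  chosen <- attr(object, "chosen")
  p <- ggplot(object, aes(x = .data$top_fraction, y = .data$ratio)) +
    geom_line() +
    geom_point(aes(colour = .data$qualifying), size = 1.5) +
    geom_hline(yintercept = attr(object, "ratio_min"), linetype = 2) +
    labs(x = "top fraction selected per study",
         y = "observed / expected genes in common",
         colour = "ratio > 2") +
    theme_minimal()
  if (!is.na(chosen)) {
    p <- p + ggplot2::geom_vline(xintercept = chosen, linetype = 3)
  }
  p
}

#' Plot meta-selection operating characteristics
#'
#' True-negative fraction against true-positive fraction, one curve per
#' index across the threshold grid.
#'
#' @param oc A [meta_operating_characteristics()] result.
#' @return A ggplot object.
#' @export
plot_operating_characteristics <- function(oc) {
  ggplot(oc, aes(x = .data$tnf, y = .data$tpf,
                 colour = .data$index_name)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "true negative fraction", y = "true positive fraction",
         colour = "index") +
    theme_minimal()
}
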