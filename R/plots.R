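## ggplot2 display of the main result types. Colors follow the field's
## convention: active magenta, inactive black/grey, PcG green, PRE orange.
class_palette <- c(
  active = "magenta3", inactive = "grey30", PcG = "forestgreen",
  PRE = "darkorange", Hp1 = "steelblue", mixed = "grey80"
)

#' Plot class-stratified enrichment densities
#'
#' Proportion-normalized density of log2 IP/Input enrichment per chromatin
#' class, the smoothed-histogram view of a genome-wide ChIP comparison.
#'
#' @param table a `chip_enrichment` tibble.
#' @param classes classes to show (see [class_density()]).
#' @return a ggplot.
#' @export
plot_class_density <- function(table, classes = c("active", "inactive", "PcG")) {
  d <- class_density(table, classes)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2_enrichment, y = .data$density,
    colour = .data$class
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = class_palette) +
    ggplot2::labs(
      x = "log2 enrichment (IP/Input)", y = "proportion of bins",
      colour = "chromatin class"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.chip_enrichment <- function(object, ...) plot_class_density(object, ...)

#' Plot per-class ChIP fold-change boxes
#'
#' Notched-box view of a [fold_change_summary()]: median, quartiles, and
#' the 1.58 IQR/sqrt(n) notch per class.
#'
#' @param fc output of [fold_change_summary()].
#' @return a ggplot.
#' @export
plot_fold_change <- function(fc) {
  s <- fc$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$class, fill = .data$class)) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      width = 0.6
    ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$median - .data$notch,
        ymax = .data$median + .data$notch
      ),
      width = 0.25, linewidth = 0.9
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_fill_manual(values = class_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "log2 fold change (IP/Input enrichment)") +
    ggplot2::theme_minimal()
}

#' Plot relative median fold-change trajectories
#'
#' Lines show the class median fold change relative to the active class
#' (which sits at 1 by construction); ribbons show the bootstrap 95% CI.
#'
#' @param x a `fc_trajectory` from [relative_median_trajectory()].
#' @return a ggplot.
#' @export
plot_trajectory <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(
    x = .data$stage, y = .data$rel_median,
    colour = .data$class, group = .data$class
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi, fill = .data$class),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = class_palette) +
    ggplot2::scale_fill_manual(values = class_palette, guide = "none") +
    ggplot2::labs(
      x = "stage", y = "median fold change relative to active",
      colour = "chromatin class"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fc_trajectory <- function(object, ...) plot_trajectory(object)

#' Plot reporter induction across development
#'
#' Mean induction per stage and line with a one-SD ribbon, faceted by
#' genotype when more than one is present.
#'
#' @param x a `reporter_trajectory` from [trajectory_table()].
#' @return a ggplot.
#' @export
plot_reporter_trajectory <- function(x) {
  p <- ggplot2::ggplot(x, ggplot2::aes(
    x = .data$stage, y = .data$mean_induction,
    colour = .data$line_id, group = .data$line_id
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_induction - .data$sd_induction,
        ymax = .data$mean_induction + .data$sd_induction,
        fill = .data$line_id
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "stage", y = "mean GFP induction (a.u.)", colour = "line") +
    ggplot2::theme_minimal() +
    ggplot2::guides(fill = "none")
  if (length(unique(x$genotype)) > 1) p <- p + ggplot2::facet_wrap(~genotype)
  p
}

#' @export
autoplot.reporter_trajectory <- function(object, ...) plot_reporter_trajectory(object)
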