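#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for germchrom result objects
#'
#' `tidy()` returns the per-observation table of a result (per-bin
#' enrichment, per-cell induction, per-contrast test statistics);
#' `glance()` returns a one-row summary.
#'
#' @param x a germchrom result object.
#' @param ... unused.
#' @name germchrom-tidiers
NULL

#' @rdname germchrom-tidiers
#' @export
tidy.chip_enrichment <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname germchrom-tidiers
#' @export
glance.chip_enrichment <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_mixed = sum(x$class == "mixed"),
    alpha = attr(x, "alpha"),
    epsilon = attr(x, "epsilon"),
    median_enrichment = median(x$enrichment)
  )
}

#' @rdname germchrom-tidiers
#' @export
tidy.induction_summary <- function(x, ...) {
  select(as_tibble(unclass(x)), -"inductions")
}

#' @rdname germchrom-tidiers
#' @export
tidy.reporter_contrast <- function(x, ...) as_tibble(unclass(x))

#' @rdname germchrom-tidiers
#' @export
glance.domain_sharing <- function(x, ...) {
  tibble(
    n_samples = x$n_samples, n_union = x$n_union,
    n_shared_all = x$n_shared_all, pct_shared = x$pct_shared
  )
}

#' @rdname germchrom-tidiers
#' @export
tidy.domain_sharing <- function(x, ...) x$by_count
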