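#' Heat-shock reporter induction statistic
#'
#' For each (line, stage, genotype) cell: the baseline is the mean
#' intensity of all non-heat-shocked replicates; each heat-shocked
#' replicate's induction is its intensity minus that baseline
#' (I = [GFP]+hs - mean [GFP]-hs). Induction is therefore invariant to
#' additive offsets in the raw intensities.
#'
#' @param records tibble (line_id, stage, genotype, heat_shock, intensity,
#'   and optionally replicate_id); each cell needs both arms.
#' @return an `induction_summary` tibble (line_id, stage, genotype, n,
#'   baseline, mean_induction, sd_induction, inductions list-column of the
#'   per-replicate values).
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   line_id = "L1", stage = "St5", genotype = "control",
#'   heat_shock = c(FALSE, FALSE, TRUE, TRUE),
#'   intensity = c(10, 10, 110, 90)
#' )
#' induction(rec) # mean induction 90
induction <- function(records) {
  needed <- c("line_id", "stage", "genotype", "heat_shock", "intensity")
  if (!all(needed %in% names(records))) {
    abort(paste("records needs columns:", paste(needed, collapse = ", ")))
  }
  out <- records %>%
    group_by(.data$line_id, .data$stage, .data$genotype) %>%
    summarise(
      n_nohs = sum(!.data$heat_shock),
      n = sum(.data$heat_shock),
      baseline = mean(.data$intensity[!.data$heat_shock]),
      inductions = list(.data$intensity[.data$heat_shock] -
        mean(.data$intensity[!.data$heat_shock])),
      .groups = "drop"
    )
  if (any(out$n_nohs == 0) || any(out$n == 0)) {
    abort("every (line, stage, genotype) cell needs both +hs and -hs replicates")
  }
  out <- out %>%
    mutate(
      mean_induction = purrr::map_dbl(.data$inductions, mean),
      sd_induction = purrr::map_dbl(.data$inductions, sd)
    ) %>%
    select(
      "line_id", "stage", "genotype", "n", "baseline",
      "mean_induction", "sd_induction", "inductions"
    )
  structure(out, class = c("induction_summary", class(out)))
}

#' Genotype contrast on reporter induction (unpaired two-tailed t)
#'
#' Pooled-variance two-sample Student's t-test comparing the induction
#' replicates of two genotypes within each (line, stage); significance
#' tiers are `**` for p < 0.01, `*` for p < 0.05, `N.S.` otherwise. An
#' optional Benjamini-Hochberg correction across the tested cells is
#' available; the default reports raw p-values.
#'
#' @param summary_a,summary_b [induction()] outputs for the two genotypes,
#'   matched on (line_id, stage). The t statistic is computed as
#'   (mean A - mean B) / pooled SE.
#' @param bh_correct adjust p-values with Benjamini-Hochberg across rows?
#' @return a `reporter_contrast` tibble (line_id, stage, genotype_a,
#'   genotype_b, n_a, n_b, t, df, p, tier).
#' @export
genotype_contrast <- function(summary_a, summary_b, bh_correct = FALSE) {
  joined <- inner_join(
    summary_a %>% select("line_id", "stage",
      genotype_a = "genotype",
      n_a = "n", ind_a = "inductions"
    ),
    summary_b %>% select("line_id", "stage",
      genotype_b = "genotype",
      n_b = "n", ind_b = "inductions"
    ),
    by = c("line_id", "stage")
  )
  if (nrow(joined) == 0) abort("no (line, stage) cells shared between the summaries")
  if (any(joined$n_a < 2) || any(joined$n_b < 2)) {
    abort("need at least 2 induction replicates per group")
  }
  stats <- purrr::pmap_dfr(
    list(joined$ind_a, joined$ind_b, joined$n_a, joined$n_b),
    function(xa, xb, na, nb) {
      sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) / (na + nb - 2)
      if (sp2 == 0) abort("zero pooled variance: t-test undefined")
      t <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
      tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
    }
  )
  out <- dplyr::bind_cols(
    joined %>% select(-"ind_a", -"ind_b"),
    stats
  )
  p_for_tier <- if (bh_correct) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$p_adj
  } else {
    out$p
  }
  out$tier <- dplyr::case_when(
    p_for_tier < 0.01 ~ "**",
    p_for_tier < 0.05 ~ "*",
    TRUE ~ "N.S."
  )
  structure(out, class = c("reporter_contrast", class(out)))
}

#' Developmental trajectory of reporter induction
#'
#' One row per (line, stage, genotype) with mean, SD, and n of the
#' induction statistic, stages ordered by `stage_order` (or their order of
#' appearance), ready for stage-vs-induction overlay plots colored by the
#' chromatin class of the insertion site.
#'
#' @param records reporter record tibble (see [induction()]).
#' @param stage_order optional character vector fixing the stage order.
#' @return a `reporter_trajectory` tibble (line_id, stage, genotype, n,
#'   mean_induction, sd_induction).
#' @export
trajectory_table <- function(records, stage_order = NULL) {
  out <- induction(records) %>%
    select("line_id", "stage", "genotype", "n", "mean_induction", "sd_induction")
  levels <- stage_order %||%
    (if (is.factor(out$stage)) levels(out$stage) else unique(as.character(out$stage)))
  out$stage <- factor(as.character(out$stage), levels = levels, ordered = TRUE)
  out <- arrange(out, .data$line_id, .data$genotype, .data$stage)
  structure(out, class = c("reporter_trajectory", class(tibble())))
}
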