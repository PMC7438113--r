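#' Transcripts per million
#'
#' Length-normalized within-sample abundance: rate_g = count_g / length_g,
#' TPM_g = 1e6 * rate_g / sum(rate) per sample, so every column sums to 1e6.
#'
#' @param counts gene x sample matrix of raw counts.
#' @param lengths per-gene effective lengths in bases (positive).
#' @return TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) abort("one length per gene required")
  if (any(lengths <= 0)) abort("gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) abort("all-zero sample column; TPM undefined")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' The reference for each gene is the geometric mean of its counts across
#' samples (genes with any zero are excluded); each sample's factor is the
#' median across genes of count / reference. This is the standard
#' median-of-ratios estimator used for sequencing-depth normalization of
#' count matrices.
#'
#' @param counts gene x sample matrix of raw counts.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) abort("no gene has nonzero counts in all samples")
  logc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(logc) # log geometric mean
  apply(logc, 2, function(x) exp(median(x - ref)))
}

#' Per-gene log2 fold change between two sample groups
#'
#' FC_g = (mean normalized count in A + prior) / (mean normalized count in
#' B + prior), reported as log2. The prior bounds fold changes of genes
#' with zero counts; as it grows all fold changes shrink to 0 (log scale).
#'
#' @param counts gene x sample matrix.
#' @param group_a,group_b disjoint column names or indices (>= 2 each).
#' @param factors per-sample size factors; computed with [size_factors()]
#'   when `NULL`.
#' @param prior_count pseudocount on the normalized scale (default 0.5).
#' @return tibble (gene_id, log2_fc).
#' @export
gene_fold_change <- function(counts, group_a, group_b, factors = NULL,
                             prior_count = 0.5) {
  counts <- as.matrix(counts)
  cols <- function(g) if (is.character(g)) match(g, colnames(counts)) else as.integer(g)
  ia <- cols(group_a)
  ib <- cols(group_b)
  if (anyNA(ia) || anyNA(ib)) abort("unknown sample columns")
  if (length(intersect(ia, ib)) > 0) abort("groups must not overlap")
  if (length(ia) < 2 || length(ib) < 2) abort("need >= 2 replicates per group")
  factors <- factors %||% size_factors(counts)
  norm <- sweep(counts, 2, factors, "/")
  fc <- (rowMeans(norm[, ia, drop = FALSE]) + prior_count) /
    (rowMeans(norm[, ib, drop = FALSE]) + prior_count)
  tibble(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    log2_fc = log2(fc)
  )
}

#' Relative median fold-change trajectory by chromatin class
#'
#' For each developmental stage (each compared to the same undifferentiated
#' baseline), takes the median fold change across the genes of each class
#' and divides it by the active-class median at that stage, so the active
#' class sits at exactly 1 throughout and repression of the other classes
#' reads directly as a relative deficit. 95% confidence intervals come from
#' a seeded nonparametric bootstrap over genes (class genes and active
#' genes resampled independently).
#'
#' @param fc_by_stage tibble (gene_id, stage, log2_fc): per-gene log2 fold
#'   change of every stage against the common baseline.
#' @param gene_classes tibble (gene_id, class).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return a `fc_trajectory` tibble (stage, class, n_genes, rel_median,
#'   ci_lo, ci_hi, reliable); `reliable` is FALSE for classes with < 10
#'   genes.
#' @export
relative_median_trajectory <- function(fc_by_stage, gene_classes, n_boot = 1000,
                                       seed = 1, conf = 0.95) {
  dat <- inner_join(fc_by_stage, gene_classes, by = "gene_id")
  if (!"active" %in% dat$class) abort("need active-class genes as the reference")
  set.seed(child_seed(seed, "trajectory"))
  a <- (1 - conf) / 2
  out <- purrr::map_dfr(unique(dat$stage), function(st) {
    d <- dplyr::filter(dat, .data$stage == st)
    fc_active <- 2^d$log2_fc[d$class == "active"]
    med_active <- median(fc_active)
    purrr::map_dfr(unique(d$class), function(cl) {
      fc <- 2^d$log2_fc[d$class == cl]
      rel <- median(fc) / med_active
      if (cl == "active") {
        ## ratio of a median to itself: identically 1, no sampling error
        return(tibble(
          stage = st, class = cl, n_genes = length(fc),
          rel_median = 1, ci_lo = 1, ci_hi = 1, reliable = length(fc) >= 10
        ))
      }
      boots <- vapply(seq_len(n_boot), function(i) {
        median(sample(fc, replace = TRUE)) /
          median(sample(fc_active, replace = TRUE))
      }, numeric(1))
      ci <- quantile(boots, c(a, 1 - a), names = FALSE)
      tibble(
        stage = st, class = cl, n_genes = length(fc), rel_median = rel,
        ci_lo = ci[1], ci_hi = ci[2], reliable = length(fc) >= 10
      )
    })
  })
  if (any(!out$reliable)) {
    warn("classes with fewer than 10 genes: confidence intervals unreliable")
  }
  structure(out, class = c("fc_trajectory", class(out)))
}
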