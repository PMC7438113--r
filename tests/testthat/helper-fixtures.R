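## Shared fixtures and brute-force oracles. Oracles are deliberately naive
## O(n*m) loops so they stay independent of the package's interval code.

small_config <- function(...) {
  args <- list(
    n_chromosomes = 1L, chrom_length = 2e5, state_mean_length = 1e4,
    ip_depth = 2e4, input_depth = 2e4, genes_per_class = 50L
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

## brute force: valid bin starts on a chromosome of length L
oracle_bin_starts <- function(L, width, step) {
  starts <- seq(0, max(0, L), by = step)
  starts[starts + width <= L]
}

## brute force: count reads whose midpoint lies in [start, end)
oracle_count_midpoints <- function(reads, start, end, chrom) {
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$species[i] != "target" || reads$chrom[i] != chrom) next
    mid <- floor((reads$start[i] + reads$end[i]) / 2)
    if (mid >= start && mid < end) n <- n + 1L
  }
  n
}

## brute force: per-base class vector of a bin under a segmentation
oracle_bin_class <- function(seg, chrom, start, end) {
  cls <- rep(NA_character_, end - start)
  for (i in seq_len(nrow(seg))) {
    if (seg$chrom[i] != chrom) next
    lo <- max(seg$start[i], start)
    hi <- min(seg$end[i], end)
    if (hi > lo) cls[(lo - start + 1):(hi - start)] <- seg$class[i]
  }
  u <- unique(cls)
  if (length(u) == 1 && !is.na(u)) u else "mixed"
}

## random four-class segmentation partitioning [0, L)
random_segmentation <- function(L, n_seg, chrom = "chr1") {
  cuts <- sort(sample(seq_len(L - 1), n_seg - 1))
  starts <- c(0, cuts)
  ends <- c(cuts, L)
  cls <- character(n_seg)
  cls[1] <- sample(c("active", "inactive", "PcG", "Hp1"), 1)
  for (k in seq_len(n_seg)[-1]) {
    cls[k] <- sample(setdiff(c("active", "inactive", "PcG", "Hp1"), cls[k - 1]), 1)
  }
  tibble::tibble(chrom = chrom, start = starts, end = ends, class = cls)
}
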