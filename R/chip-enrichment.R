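#' Bundle reads into a ChIP sample library
#'
#' Attaches sample metadata and tallies target vs spike-in reads (by the
#' `species` tag carried over from a hybrid-genome style alignment).
#'
#' @param reads tibble (species, chrom, start, end); `species` must be
#'   `"target"` or `"spike"`.
#' @param sample_id sample label.
#' @param role `"IP"` or `"Input"`.
#' @return a `chip_library` list with `reads`, `target_count`, `spike_count`.
#' @export
chip_library <- function(reads, sample_id = "sample", role = c("IP", "Input")) {
  role <- match.arg(role)
  check_intervals(reads, "reads", c("species", "chrom", "start", "end"))
  if (nrow(reads) > 0 && !all(reads$species %in% c("target", "spike"))) {
    abort("reads$species must be 'target' or 'spike'")
  }
  structure(
    list(
      sample_id = sample_id, role = role, reads = reads,
      target_count = sum(reads$species == "target"),
      spike_count = sum(reads$species == "spike")
    ),
    class = "chip_library"
  )
}

#' @export
print.chip_library <- function(x, ...) {
  cat(
    "<chip_library> ", x$sample_id, " (", x$role, "): ",
    x$target_count, " target + ", x$spike_count, " spike reads\n",
    sep = ""
  )
  invisible(x)
}

#' Count target-read midpoints per (overlapping) bin
#'
#' Each target read contributes to every bin whose `[start, end)` interval
#' contains its midpoint, so with overlapping bins one read is counted in
#' width/step bins. Spike reads never count.
#'
#' @param library a [chip_library()] (or a raw read tibble).
#' @param bins bin tibble (chrom, start, end).
#' @return integer vector of counts, one per bin row.
#' @export
count_reads_per_bin <- function(library, bins) {
  reads <- if (inherits(library, "chip_library")) library$reads else library
  check_intervals(bins, "bins")
  counts <- integer(nrow(bins))
  reads <- reads[reads$species == "target", ]
  if (nrow(reads) == 0 || nrow(bins) == 0) {
    return(counts)
  }
  mid <- floor((reads$start + reads$end) / 2)
  for (ch in intersect(unique(bins$chrom), unique(reads$chrom))) {
    ib <- which(bins$chrom == ch)
    m <- mid[reads$chrom == ch]
    br <- IRanges::IRanges(bins$start[ib] + 1L, bins$end[ib])
    mr <- IRanges::IRanges(m + 1L, m + 1L)
    counts[ib] <- IRanges::countOverlaps(br, mr)
  }
  counts
}

#' Scale counts to reads per million (RPM)
#'
#' @param counts numeric vector of raw counts.
#' @param target_total total target reads in the library; must be positive.
#' @return counts * 1e6 / target_total.
#' @export
rpm_scale <- function(counts, target_total) {
  if (length(target_total) != 1 || target_total <= 0) {
    abort("target_total must be a single positive count")
  }
  counts * 1e6 / target_total
}

#' Spike-in normalization factor for an IP/Input pair
#'
#' alpha = (spike fraction of Input) / (spike fraction of IP). Multiplying
#' the IP RPM track by alpha makes signal comparable across samples on the
#' spike-in scale: a genome-wide gain of target signal dilutes the IP spike
#' fraction and thus raises alpha-scaled signal proportionally.
#'
#' @param ip,input [chip_library()] objects; both need spike reads.
#' @return alpha (positive scalar).
#' @export
spike_normalization_factor <- function(ip, input) {
  stopifnot(inherits(ip, "chip_library"), inherits(input, "chip_library"))
  if (ip$spike_count == 0 || input$spike_count == 0) {
    abort(paste(
      "no spike-in reads in one of the libraries;",
      "run with spike_norm = FALSE (alpha = 1) for unnormalized enrichment"
    ))
  }
  f_input <- input$spike_count / (input$target_count + input$spike_count)
  f_ip <- ip$spike_count / (ip$target_count + ip$spike_count)
  f_input / f_ip
}

#' Per-bin spike-normalized IP/Input enrichment
#'
#' E_b = (alpha * ip_rpm_b + epsilon) / (input_rpm_b + epsilon). The
#' pseudocount bounds log-ratios on empty bins without affecting typically
#' covered ones.
#'
#' @param bins classified bin tibble.
#' @param ip_rpm,input_rpm RPM vectors matching `bins` row for row.
#' @param alpha spike-in normalization factor (1 = none).
#' @param epsilon pseudocount in RPM units.
#' @return a `chip_enrichment` tibble: bins plus `ip_rpm`, `input_rpm`,
#'   `enrichment`; `alpha` and `epsilon` stored as attributes.
#' @export
bin_enrichment <- function(bins, ip_rpm, input_rpm, alpha = 1, epsilon = 0) {
  if (length(ip_rpm) != nrow(bins) || length(input_rpm) != nrow(bins)) {
    abort("ip_rpm and input_rpm must match the bin list row for row")
  }
  if (alpha <= 0 || epsilon < 0) abort("alpha must be positive and epsilon non-negative")
  out <- bins
  out$ip_rpm <- ip_rpm
  out$input_rpm <- input_rpm
  out$enrichment <- (alpha * ip_rpm + epsilon) / (input_rpm + epsilon)
  structure(as_tibble(out),
    alpha = alpha, epsilon = epsilon,
    class = c("chip_enrichment", class(as_tibble(out)))
  )
}

#' One-call enrichment table from an IP/Input library pair
#'
#' Counts target-read midpoints per bin, scales both tracks to RPM, derives
#' the spike normalization factor (optional), and applies the default
#' pseudocount: the RPM equivalent of one read in the smaller library.
#'
#' @param ip,input [chip_library()] objects.
#' @param bins classified bin tibble.
#' @param spike_norm derive alpha from the spike-in read proportions?
#' @param epsilon pseudocount in RPM; default one-read RPM of the smaller
#'   library.
#' @return a `chip_enrichment` tibble (see [bin_enrichment()]).
#' @export
enrichment_table <- function(ip, input, bins, spike_norm = TRUE, epsilon = NULL) {
  if (input$target_count == 0 || ip$target_count == 0) {
    abort("both libraries need target reads")
  }
  alpha <- if (spike_norm) spike_normalization_factor(ip, input) else 1
  epsilon <- epsilon %||% (1e6 / min(ip$target_count, input$target_count))
  bin_enrichment(
    bins,
    ip_rpm = rpm_scale(count_reads_per_bin(ip, bins), ip$target_count),
    input_rpm = rpm_scale(count_reads_per_bin(input, bins), input$target_count),
    alpha = alpha, epsilon = epsilon
  )
}

#' Class-stratified density of log2 enrichment
#'
#' Gaussian kernel density of log2(E) computed separately within each
#' class, so every curve integrates to 1 regardless of how many bins the
#' class has (proportion of bins, not raw number). Bandwidth follows
#' Silverman's rule by default.
#'
#' @param table a `chip_enrichment` tibble.
#' @param classes classes to include; `"PRE"` selects PcG bins with
#'   `pre_flag` set (and `"PcG"` then means PRE-lacking PcG bins).
#' @param bw density bandwidth (passed to [stats::density()]).
#' @param n grid size.
#' @return tibble (class, log2_enrichment, density).
#' @export
class_density <- function(table, classes = c("active", "inactive", "PcG"),
                          bw = "nrd0", n = 512) {
  out <- purrr::map_dfr(classes, function(cl) {
    x <- log2(select_class_bins(table, cl)$enrichment)
    if (length(x) == 0) {
      warn(paste0("no bins in class '", cl, "'; omitted"))
      return(tibble())
    }
    d <- density(x, bw = bw, n = n)
    tibble(class = cl, log2_enrichment = d$x, density = d$y)
  })
  out
}

## internal: rows of an enrichment/bin table belonging to a summary class,
## where "PRE" = PcG & pre_flag and "PcG" excludes PRE bins when flagged
select_class_bins <- function(table, cl) {
  has_flag <- "pre_flag" %in% names(table)
  if (cl == "PRE") {
    if (!has_flag) abort("PRE class requested but bins carry no pre_flag")
    dplyr::filter(table, .data$class == "PcG", .data$pre_flag)
  } else if (cl == "PcG" && has_flag) {
    dplyr::filter(table, .data$class == "PcG", !.data$pre_flag)
  } else {
    dplyr::filter(table, .data$class == cl)
  }
}

#' Call domains enriched for ChIP signal
#'
#' A domain's enrichment is the mean E over class-assigned (non-mixed) bins
#' lying fully inside it; the domain is called enriched when that mean
#' reaches `threshold`. Domains smaller than `min_size` are dropped up
#' front; domains containing no usable bin get an `NA` call.
#'
#' @param domains segment tibble (chrom, start, end, class); typically the
#'   merged four-class domains of one cell type.
#' @param table a `chip_enrichment` tibble whose bins carry classes.
#' @param threshold mean-enrichment cutoff (default 2).
#' @param min_size smallest domain considered, bases (default 10000).
#' @return tibble (chrom, start, end, class, n_bins, mean_enrichment,
#'   enriched).
#' @export
call_domains <- function(domains, table, threshold = 2, min_size = 10000) {
  check_intervals(domains, "domains", c("chrom", "start", "end", "class"))
  domains <- dplyr::filter(domains, .data$end - .data$start >= min_size)
  usable <- dplyr::filter(table, .data$class != "mixed")
  out <- domains
  out$n_bins <- 0L
  out$mean_enrichment <- NA_real_
  for (ch in intersect(unique(domains$chrom), unique(usable$chrom))) {
    id <- which(out$chrom == ch)
    tab <- usable[usable$chrom == ch, ]
    dr <- IRanges::IRanges(out$start[id] + 1L, out$end[id])
    br <- IRanges::IRanges(tab$start + 1L, tab$end)
    ov <- IRanges::findOverlaps(br, dr, type = "within")
    if (length(ov) == 0) next
    agg <- tibble(
      dom = S4Vectors::subjectHits(ov),
      e = tab$enrichment[S4Vectors::queryHits(ov)],
      ok = tab$class[S4Vectors::queryHits(ov)] == out$class[id][S4Vectors::subjectHits(ov)]
    ) %>%
      dplyr::filter(.data$ok) %>%
      group_by(.data$dom) %>%
      summarise(n = dplyr::n(), m = mean(.data$e), .groups = "drop")
    out$n_bins[id[agg$dom]] <- agg$n
    out$mean_enrichment[id[agg$dom]] <- agg$m
  }
  out$enriched <- out$mean_enrichment >= threshold
  attr(out, "threshold") <- threshold
  out
}

#' Summarise domain sharing across samples
#'
#' Given enrichment calls for the same domain list in several samples,
#' counts how many domains are enriched in all, some, or none of them and
#' the percentage shared = 100 * |enriched in all| / |enriched in any|.
#'
#' @param calls either a logical matrix/data frame (rows = domains, columns
#'   = samples; `NA` treated as not enriched) or a named list of
#'   [call_domains()] outputs over the same domain rows.
#' @return a `domain_sharing` list with `by_count` (tibble: n_samples,
#'   n_domains), `n_union`, `n_shared_all`, `pct_shared`.
#' @export
share_domains <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls) && !is.matrix(calls)) {
    mat <- do.call(cbind, lapply(calls, function(x) x$enriched))
  } else {
    mat <- as.matrix(calls)
  }
  mode(mat) <- "logical"
  mat[is.na(mat)] <- FALSE
  k <- rowSums(mat)
  n_union <- sum(k > 0)
  n_all <- sum(k == ncol(mat))
  structure(
    list(
      by_count = dplyr::count(tibble(n_samples = k[k > 0]), .data$n_samples,
        name = "n_domains"
      ),
      n_samples = ncol(mat),
      n_union = n_union,
      n_shared_all = n_all,
      pct_shared = if (n_union > 0) 100 * n_all / n_union else NA_real_
    ),
    class = "domain_sharing"
  )
}

#' @export
print.domain_sharing <- function(x, ...) {
  cat(
    "<domain_sharing> ", x$n_shared_all, "/", x$n_union,
    " domains enriched in all ", x$n_samples, " samples (",
    format(x$pct_shared, digits = 3), "% shared)\n",
    sep = ""
  )
  invisible(x)
}

#' Per-bin enrichment fold changes between two samples
#'
#' Computes log2(E_A / E_B) for every bin and boxplot summary statistics
#' per chromatin class, splitting PcG bins into PRE-containing and
#' PRE-lacking when the bins carry a `pre_flag`. The notch half-width
#' 1.58 * IQR / sqrt(n) is the conventional ~95% confidence interval of
#' the median.
#'
#' @param table_a,table_b `chip_enrichment` tibbles over identical bins.
#' @param classes summary classes (see [class_density()] for `"PRE"`).
#' @return list with `per_bin` (bins + log2_fc) and `summary` (tibble:
#'   class, n, median, q1, q3, notch).
#' @export
fold_change_summary <- function(table_a, table_b,
                                classes = c("inactive", "PcG", "PRE")) {
  same <- nrow(table_a) == nrow(table_b) &&
    all(table_a$chrom == table_b$chrom) &&
    all(table_a$start == table_b$start)
  if (!same) abort("the two tables must cover identical bin lists")
  per_bin <- table_a %>%
    select(-"ip_rpm", -"input_rpm", -"enrichment") %>%
    mutate(log2_fc = log2(table_a$enrichment / table_b$enrichment))
  summary <- purrr::map_dfr(classes, function(cl) {
    x <- select_class_bins(per_bin, cl)$log2_fc
    if (length(x) == 0) {
      return(tibble())
    }
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(
      class = cl, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
      notch = 1.58 * (q[3] - q[1]) / sqrt(length(x))
    )
  })
  list(per_bin = per_bin, summary = summary)
}

#' Peak-centered raw read-depth matrix
#'
#' Builds a summits x positions matrix of raw target-read midpoint counts
#' in `binsize` cells across a `window` centered on each summit, the input
#' of peak-centered heatmaps. Rows are ordered by decreasing row sum.
#' Cells extending past a chromosome end are `NA`.
#'
#' @param library a [chip_library()] (or raw read tibble).
#' @param summits tibble (chrom, pos).
#' @param chrom_sizes tibble (chrom, length) or named vector.
#' @param window total window width, bases (default 20000, i.e. +/-10 kb).
#' @param binsize cell width, bases.
#' @param order_rows order rows by decreasing total depth?
#' @return numeric matrix with one row per summit; attribute `summits`
#'   records the (reordered) summit table.
#' @export
peak_matrix <- function(library, summits, chrom_sizes, window = 20000,
                        binsize = 500, order_rows = TRUE) {
  if (nrow(summits) < 1) abort("need at least one summit")
  reads <- if (inherits(library, "chip_library")) library$reads else library
  reads <- reads[reads$species == "target", ]
  if (!is.data.frame(chrom_sizes)) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), length = unname(chrom_sizes))
  }
  half <- window / 2
  n_cell <- floor(window / binsize)
  offsets <- seq(-half, by = binsize, length.out = n_cell)
  mat <- matrix(0, nrow = nrow(summits), ncol = n_cell)
  colnames(mat) <- offsets
  mid <- floor((reads$start + reads$end) / 2)
  for (i in seq_len(nrow(summits))) {
    ch <- summits$chrom[i]
    p <- summits$pos[i]
    L <- chrom_sizes$length[match(ch, chrom_sizes$chrom)]
    cell_start <- p + offsets
    cell_end <- cell_start + binsize
    oob <- cell_start < 0 | cell_end > (L %||% Inf)
    m <- mid[reads$chrom == ch]
    idx <- floor((m - (p - half)) / binsize) + 1
    idx <- idx[idx >= 1 & idx <= n_cell]
    if (length(idx) > 0) mat[i, ] <- tabulate(idx, nbins = n_cell)
    mat[i, oob] <- NA_real_
  }
  if (order_rows && nrow(mat) > 1) {
    ord <- order(rowSums(mat, na.rm = TRUE), decreasing = TRUE)
    mat <- mat[ord, , drop = FALSE]
    summits <- summits[ord, ]
  }
  attr(mat, "summits") <- summits
  mat
}

#' Enrichment in the 500 b window downstream of each TSS
#'
#' Strand-aware: for a + strand TSS at p the window is `[p, p + width)`;
#' for a - strand TSS it is `[p - width, p)`. TSSs whose window extends
#' past a chromosome end yield `NA` and are marked `out_of_range`.
#'
#' @param ip,input [chip_library()] objects.
#' @param tss tibble (gene_id, chrom, pos, strand).
#' @param chrom_sizes tibble (chrom, length) or named vector.
#' @param width window width, bases (default 500).
#' @param spike_norm,epsilon as in [enrichment_table()].
#' @return tibble (gene_id, chrom, start, end, enrichment, out_of_range).
#' @export
tss_window_enrichment <- function(ip, input, tss, chrom_sizes, width = 500,
                                  spike_norm = TRUE, epsilon = NULL) {
  stopifnot(all(tss$strand %in% c("+", "-")))
  if (!is.data.frame(chrom_sizes)) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), length = unname(chrom_sizes))
  }
  win <- tss %>%
    mutate(
      start = ifelse(.data$strand == "+", .data$pos, .data$pos - width),
      end = ifelse(.data$strand == "+", .data$pos + width, .data$pos),
      chrom_len = chrom_sizes$length[match(.data$chrom, chrom_sizes$chrom)],
      out_of_range = .data$start < 0 | .data$end > .data$chrom_len
    )
  ok <- dplyr::filter(win, !.data$out_of_range) %>% select("chrom", "start", "end")
  e <- rep(NA_real_, nrow(win))
  if (nrow(ok) > 0) {
    tab <- enrichment_table(ip, input, ok, spike_norm = spike_norm, epsilon = epsilon)
    e[!win$out_of_range] <- tab$enrichment
  }
  win %>%
    mutate(enrichment = e) %>%
    select("gene_id", "chrom", "start", "end", "enrichment", "out_of_range")
}
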