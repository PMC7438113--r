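#' Simplify a nine-state chromatin segmentation to four classes
#'
#' States 1-5 become `active`, state 6 `PcG`, states 7-8 `Hp1`, and state 9
#' `inactive`. Adjacent touching segments that end up in the same class are
#' merged.
#'
#' @param segments_9state tibble (chrom, start, end, state) with integer
#'   states 1-9, sorted and non-overlapping within each chromosome.
#' @return tibble (chrom, start, end, class).
#' @export
#' @examples
#' simplify_states(tibble::tibble(
#'   chrom = "2L", start = c(0, 100, 300), end = c(100, 300, 500),
#'   state = c(2, 4, 6)
#' ))
simplify_states <- function(segments_9state) {
  check_intervals(segments_9state, "segments_9state", c("chrom", "start", "end", "state"))
  s <- segments_9state$state
  if (nrow(segments_9state) > 0 &&
    (any(is.na(s)) || any(s != round(s)) || any(s < 1) || any(s > 9))) {
    abort("unknown chromatin state label; states must be integers 1-9")
  }
  map <- c(rep("active", 5), "PcG", "Hp1", "Hp1", "inactive")
  out <- segments_9state %>%
    mutate(class = map[.data$state]) %>%
    select("chrom", "start", "end", "class") %>%
    arrange(.data$chrom, .data$start)
  merge_adjacent_segments(out)
}

## merge touching, same-class neighbours (per chromosome)
merge_adjacent_segments <- function(segments) {
  segments %>%
    group_by(.data$chrom) %>%
    mutate(
      new_run = row_number() == 1 |
        .data$class != lag(.data$class) | .data$start != lag(.data$end),
      run = cumsum(.data$new_run)
    ) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      class = .data$class[1], .groups = "drop"
    ) %>%
    select("chrom", "start", "end", "class") %>%
    arrange(.data$chrom, .data$start)
}

#' Tile chromosomes with fixed-width overlapping bins
#'
#' Bins of `width` bases start every `step` bases at 0, step, 2*step, ...;
#' bins extending past the chromosome end are dropped, as are bins on
#' excluded chromosomes or overlapping any masked interval (a bin partially
#' overlapping a mask is dropped entirely).
#'
#' @param chrom_sizes tibble (chrom, length) or named numeric vector.
#' @param width bin width in bases (default 5000).
#' @param step bin start spacing in bases (default 500).
#' @param mask optional exclusion mask: tibble (chrom, start, end) of
#'   intervals to avoid (e.g. amplified chorion clusters, pericentric
#'   heterochromatin).
#' @param exclude_chroms character vector of chromosomes to drop wholesale
#'   (e.g. Y, the 4th, unplaced scaffolds).
#' @return tibble (chrom, start, end).
#' @export
make_bins <- function(chrom_sizes, width = 5000, step = 500, mask = NULL,
                      exclude_chroms = character()) {
  if (width <= 0 || step <= 0) abort("width and step must be positive")
  if (!is.data.frame(chrom_sizes)) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), length = unname(chrom_sizes))
  }
  chrom_sizes <- dplyr::filter(chrom_sizes, !.data$chrom %in% exclude_chroms)

  bins <- purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    L <- chrom_sizes$length[i]
    if (L < width) {
      return(tibble())
    }
    starts <- seq(0, L - width, by = step)
    tibble(chrom = chrom_sizes$chrom[i], start = starts, end = starts + width)
  })
  if (!is.null(mask) && nrow(bins) > 0 && nrow(mask) > 0) {
    check_intervals(mask, "mask")
    hit <- overlaps_any(bins, mask)
    bins <- bins[!hit, ]
  }
  bins
}

## internal: logical, does each interval in x overlap any interval in y
overlaps_any <- function(x, y) {
  hit <- logical(nrow(x))
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    ix <- which(x$chrom == ch)
    xr <- IRanges::IRanges(x$start[ix] + 1L, x$end[ix])
    yr <- with(y[y$chrom == ch, ], IRanges::IRanges(start + 1L, end))
    hit[ix] <- IRanges::overlapsAny(xr, yr)
  }
  hit
}

#' Assign each bin the single chromatin class covering it
#'
#' A bin receives a class only when segments of exactly one class cover
#' every base of the bin; bins spanning two classes or uncovered sequence
#' are labeled `mixed` and are excluded from class-stratified analyses
#' (domain edges are thereby slightly underrepresented).
#'
#' @param bins tibble (chrom, start, end).
#' @param segments sorted, non-overlapping four-class segment tibble.
#' @return `bins` with a `class` column (`active`, `inactive`, `PcG`,
#'   `Hp1`, or `mixed`).
#' @export
assign_bin_class <- function(bins, segments) {
  check_intervals(bins, "bins")
  check_intervals(segments, "segments", c("chrom", "start", "end", "class"))
  bins$class <- "mixed"
  if (nrow(bins) == 0) {
    return(bins)
  }
  for (ch in intersect(unique(bins$chrom), unique(segments$chrom))) {
    ib <- which(bins$chrom == ch)
    seg <- segments[segments$chrom == ch, ]
    br <- IRanges::IRanges(bins$start[ib] + 1L, bins$end[ib])
    sr <- IRanges::IRanges(seg$start + 1L, seg$end)
    ov <- IRanges::findOverlaps(br, sr)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      br[S4Vectors::queryHits(ov)], sr[S4Vectors::subjectHits(ov)]
    ))
    per_pair <- tibble(
      bin = S4Vectors::queryHits(ov),
      class = seg$class[S4Vectors::subjectHits(ov)],
      w = w
    ) %>%
      group_by(.data$bin, .data$class) %>%
      summarise(w = sum(.data$w), .groups = "drop_last") %>%
      summarise(
        n_class = dplyr::n(), cover = sum(.data$w),
        class = .data$class[which.max(.data$w)], .groups = "drop"
      )
    full <- per_pair$n_class == 1 & per_pair$cover == IRanges::width(br)[per_pair$bin]
    bins$class[ib[per_pair$bin[full]]] <- per_pair$class[full]
  }
  bins
}

#' Flag PcG bins that contain a PRE peak summit
#'
#' A PcG-class bin is flagged when at least one summit position from the
#' composite (deduplicated) summit list falls in `[start, end)`. Bins of
#' other classes are never flagged.
#'
#' @param bins classified bin tibble (needs `class`).
#' @param summits tibble (chrom, pos) of peak summit positions.
#' @return `bins` with a logical `pre_flag` column.
#' @export
flag_pre_bins <- function(bins, summits) {
  check_intervals(bins, "bins", c("chrom", "start", "end", "class"))
  summits <- distinct(summits, .data$chrom, .data$pos)
  bins$pre_flag <- FALSE
  for (ch in intersect(unique(bins$chrom), unique(summits$chrom))) {
    ib <- which(bins$chrom == ch & bins$class == "PcG")
    if (length(ib) == 0) next
    pos <- summits$pos[summits$chrom == ch]
    br <- IRanges::IRanges(bins$start[ib] + 1L, bins$end[ib])
    pr <- IRanges::IRanges(pos + 1L, pos + 1L) # point, half-open [pos, pos+1)
    bins$pre_flag[ib] <- IRanges::overlapsAny(br, pr)
  }
  bins
}

#' Collapse gene isoforms to their largest shared region
#'
#' Returns the intersection of all isoform spans: the largest interval
#' contained in every isoform. Genes whose isoforms share no sequence
#' collapse to an empty (zero-row) result.
#'
#' @param isoforms tibble (start, end) of isoform spans (optionally with a
#'   `chrom` column, which must be constant).
#' @return one-row tibble (start, end), or a zero-row tibble if empty.
#' @export
collapse_isoforms <- function(isoforms) {
  if (nrow(isoforms) < 1) abort("need at least one isoform")
  if ("chrom" %in% names(isoforms) && length(unique(isoforms$chrom)) > 1) {
    abort("isoforms lie on different chromosomes")
  }
  s <- max(isoforms$start)
  e <- min(isoforms$end)
  if (e <= s) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  tibble(start = s, end = e)
}

#' Classify genes by chromatin domain with PcG > active > inactive precedence
#'
#' A gene overlapping any PcG segment by at least one base is a PcG gene;
#' otherwise overlapping any active segment makes it active; all remaining
#' genes are inactive. Genes on excluded chromosomes should be removed
#' upstream.
#'
#' @param genes tibble (chrom, start, end) of collapsed gene intervals.
#' @param segments four-class segment tibble.
#' @return `genes` with a `class` column.
#' @export
classify_genes <- function(genes, segments) {
  check_intervals(genes, "genes")
  if (nrow(genes) > 0 && any(genes$end - genes$start <= 0)) {
    abort("empty collapsed interval; drop such genes before classification")
  }
  check_intervals(segments, "segments", c("chrom", "start", "end", "class"))
  genes$class <- "inactive"
  for (cl in c("active", "PcG")) { # PcG applied last so it wins
    hit <- overlaps_any(genes, dplyr::filter(segments, .data$class == cl))
    genes$class[hit] <- cl
  }
  genes
}

#' Span of a domain coordinate string, in kilobases
#'
#' Parses strings of the form `"ARM:START..END"` and returns
#' `(END - START) / 1000`, the convention under which a domain printed as
#' `2L:2198000..2209000` has length 11 kb.
#'
#' @param coordinate_string character vector of `"ARM:START..END"` strings.
#' @return numeric vector of spans in kb.
#' @export
#' @examples
#' domain_span_kb("2L:2198000..2209000") # 11
domain_span_kb <- function(coordinate_string) {
  m <- stringr::str_match(
    trimws(coordinate_string),
    "^([A-Za-z0-9_]+):([0-9]+)\\.\\.([0-9]+)$"
  )
  if (any(is.na(m[, 1]))) {
    bad <- coordinate_string[is.na(m[, 1])][1]
    abort(paste0("malformed coordinate string: '", bad, "' (expected ARM:START..END)"))
  }
  start <- as.numeric(m[, 3])
  end <- as.numeric(m[, 4])
  if (any(end <= start)) abort("END must exceed START in coordinate strings")
  (end - start) / 1000
}
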