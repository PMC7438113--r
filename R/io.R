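#' Read a BED file into a 0-based half-open interval tibble
#'
#' Accepts 3-12 columns; the first six are named chrom, start, end, name,
#' score, strand, extras keep `X7`... Lines starting with `#`, `track`, or
#' `browser` are skipped. Invalid coordinates raise a parse error naming
#' the offending data line.
#'
#' @param path file path.
#' @param chrom_sizes optional tibble/named vector; when given, intervals
#'   on unknown chromosomes are an error.
#' @return tibble with at least chrom, start, end.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  dat <- readr::read_tsv(I(lines[keep]),
    col_names = FALSE, show_col_types = FALSE,
    progress = FALSE
  )
  if (ncol(dat) < 3 || ncol(dat) > 12) {
    abort("BED files must have between 3 and 12 columns")
  }
  std <- c("chrom", "start", "end", "name", "score", "strand")
  names(dat)[seq_len(min(ncol(dat), 6))] <- std[seq_len(min(ncol(dat), 6))]
  dat$start <- suppressWarnings(as.numeric(dat$start))
  dat$end <- suppressWarnings(as.numeric(dat$end))
  line_no <- which(keep) # original file line numbers
  bad <- which(is.na(dat$start) | is.na(dat$end) | dat$start < 0 | dat$end <= dat$start)
  if (length(bad) > 0) {
    abort(paste0(
      "invalid BED interval at line ", line_no[bad[1]], " of ", path,
      " (need 0 <= start < end)"
    ))
  }
  if (!is.null(chrom_sizes)) {
    known <- if (is.data.frame(chrom_sizes)) chrom_sizes$chrom else names(chrom_sizes)
    bad <- which(!dat$chrom %in% known)
    if (length(bad) > 0) {
      abort(paste0("unknown chromosome '", dat$chrom[bad[1]], "' at line ", line_no[bad[1]]))
    }
  }
  as_tibble(dat)
}

#' Write intervals to BED
#'
#' Writes chrom/start/end plus any of name, score, strand present, in BED
#' column order. Round-trips with [read_bed()].
#'
#' @param x interval tibble.
#' @param path output path.
#' @param extra_cols additional columns to append after the standard six
#'   (e.g. `class`, `pre_flag`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = character()) {
  check_intervals(x, "intervals")
  std <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  ## BED is positional: pad through the last present standard column
  need <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- max(match(std, need))
  out <- tibble(.rows = nrow(x))
  for (col in need[seq_len(upto)]) {
    out[[col]] <- if (col %in% names(x)) {
      x[[col]]
    } else if (col == "name") "." else if (col == "score") 0 else "."
  }
  for (col in extra_cols) out[[col]] <- x[[col]]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write / read a tabular result as commented-header TSV
#'
#' All tabular pipeline outputs are TSV with a single header line starting
#' `#`, so files are both greppable and spreadsheet-safe.
#'
#' @param x data frame.
#' @param path file path.
#' @return `path` (write) or a tibble (read), invisibly for write.
#' @export
write_tsv_commented <- function(x, path) {
  x <- dplyr::select(as_tibble(x), -dplyr::where(is.list))
  header <- paste0("#", paste(names(x), collapse = "\t"))
  readr::write_lines(header, path)
  readr::write_tsv(x, path, col_names = FALSE, append = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_tsv_commented
#' @export
read_tsv_commented <- function(path) {
  header <- sub("^#", "", readr::read_lines(path, n_max = 1))
  dat <- readr::read_tsv(path,
    col_names = strsplit(header, "\t")[[1]], skip = 1,
    show_col_types = FALSE, progress = FALSE
  )
  as_tibble(dat)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [sim_config()] or plain named list.
#' @return [read_config()] returns a `sim_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("class_weights", "enrichment_multipliers", "class_log2fc")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
  }), path)
  invisible(path)
}
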