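#' Run the full synthetic-data pipeline end to end
#'
#' Generates a toy four-class genome, simulates spike-in tagged ChIP
#' libraries for a control and a PcG-depleted ("knockdown") sample,
#' computes spike-normalized bin enrichment, domain calls, cross-sample
#' sharing, and per-class fold changes, simulates and analyses expression
#' counts and reporter fluorescence, and writes every table plus a
#' machine-readable run manifest to `out_dir`. Deterministic for a given
#' config and seed; every stage derives its own child seed by hashing the
#' stage name.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param seed master seed; defaults to `config$seed`.
#' @param knockdown_pcg_factor multiplier applied to the PcG IP rate in the
#'   simulated knockdown sample (default 0.5, i.e. a twofold loss).
#' @param threshold domain-call enrichment threshold (default 2).
#' @param spike_norm use spike-in normalization (else alpha = 1).
#' @param n_reps_expression expression replicates per condition.
#' @param verbose log each stage with [message()]?
#' @return invisibly, a list with the in-memory results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed,
                         knockdown_pcg_factor = 0.5, threshold = 2,
                         spike_norm = TRUE, n_reps_expression = 3L,
                         verbose = FALSE) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[germchrom] ", ...)
  config$seed <- as.integer(seed)
  files <- character()
  put <- function(x, name, writer = write_tsv_commented) {
    path <- file.path(out_dir, name)
    writer(x, path)
    files[[name]] <<- path
    path
  }

  ## --- genome ---------------------------------------------------------
  say("genome: ", config$n_chromosomes, " chromosomes x ", config$chrom_length, " b")
  genome <- generate_genome(config)
  segments <- genome$segments
  genes <- genome$genes
  chrom_sizes <- segments %>%
    group_by(chrom = .data$chrom) %>%
    summarise(length = max(.data$end), .groups = "drop")
  put(segments, "segments.bed", function(x, p) write_bed(x, p, extra_cols = "class"))
  put(dplyr::select(genes, -"isoforms"), "genes.tsv")

  ## --- bins -----------------------------------------------------------
  bins <- make_bins(chrom_sizes) %>% assign_bin_class(segments)
  summits <- segments %>%
    dplyr::filter(.data$class == "PcG") %>%
    mutate(pos = floor((.data$start + .data$end) / 2)) %>%
    select("chrom", "pos")
  bins <- flag_pre_bins(bins, summits)
  say(
    "bins: ", nrow(bins), " total; per class: ",
    paste(names(table(bins$class)), table(bins$class), sep = "=", collapse = " ")
  )
  put(bins, "bins.tsv")

  ## --- ChIP: control and knockdown ------------------------------------
  cfg_kd <- config
  cfg_kd$enrichment_multipliers["PcG"] <-
    cfg_kd$enrichment_multipliers["PcG"] * knockdown_pcg_factor
  cfg_kd$seed <- child_seed(seed, "knockdown")
  tables <- purrr::imap(list(control = config, knockdown = cfg_kd), function(cfg, nm) {
    say("ChIP (", nm, "): ", cfg$ip_depth, " IP + ", cfg$input_depth, " Input reads")
    libs <- simulate_chip_pair(segments, cfg)
    tab <- enrichment_table(
      chip_library(libs$ip, paste0(nm, "_IP"), "IP"),
      chip_library(libs$input, paste0(nm, "_Input"), "Input"),
      bins,
      spike_norm = spike_norm
    )
    put(tab, paste0("enrichment_", nm, ".tsv"))
    put(
      select(tab, "chrom", "start", "end", "enrichment"),
      paste0("enrichment_", nm, ".bedgraph"),
      function(x, p) readr::write_tsv(x, p, col_names = FALSE, progress = FALSE)
    )
    tab
  })
  alphas <- purrr::map_dbl(tables, ~ attr(.x, "alpha"))

  domains <- merge_adjacent_segments(segments)
  calls <- purrr::imap(tables, function(tab, nm) {
    cd <- call_domains(
      dplyr::filter(domains, .data$class == "PcG"), tab,
      threshold = threshold
    )
    put(cd, paste0("domain_calls_", nm, ".tsv"))
    cd
  })
  sharing <- share_domains(calls)
  put(
    tibble(
      n_samples = sharing$n_samples, n_union = sharing$n_union,
      n_shared_all = sharing$n_shared_all, pct_shared = sharing$pct_shared
    ),
    "sharing_summary.tsv"
  )
  fc_chip <- fold_change_summary(tables$knockdown, tables$control)
  put(fc_chip$summary, "chip_fold_change_summary.tsv")

  ## --- expression ------------------------------------------------------
  say("expression: ", nrow(genes), " genes x 2 conditions")
  es <- simulate_expression(genes, config, n_reps_per_condition = n_reps_expression)
  put(
    as_tibble(es$counts, rownames = "gene_id"),
    "expression_counts.tsv"
  )
  fc <- gene_fold_change(
    es$counts,
    group_a = es$samples$sample_id[es$samples$condition == "B"],
    group_b = es$samples$sample_id[es$samples$condition == "A"]
  ) %>%
    left_join(select(es$genes, "gene_id", "class"), by = "gene_id")
  put(fc, "expression_fold_change.tsv")
  fc_class <- fc %>%
    group_by(class = .data$class) %>%
    summarise(
      n = dplyr::n(),
      median_fc = median(2^.data$log2_fc),
      notch = 1.58 * IQR(2^.data$log2_fc) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  put(fc_class, "expression_class_summary.tsv")

  ## --- reporter --------------------------------------------------------
  stages <- c("GSC", "R2A", "St1", "St5")
  lines <- c(active = "line_active", inactive = "line_inactive", PcG = "line_PcG")
  silencing <- tidyr::expand_grid(
    line_id = unname(lines), stage = stages,
    genotype = c("control", "knockdown")
  ) %>%
    mutate(silencing_factor = ifelse(
      .data$genotype == "control" & .data$line_id != "line_active" &
        .data$stage != "GSC",
      config$silencing_factor, 1
    ))
  say("reporter: ", length(lines), " lines x ", length(stages), " stages")
  records <- simulate_reporter(unname(lines), stages, c("control", "knockdown"),
    config,
    silencing = silencing
  )
  put(records, "reporter_records.tsv")
  ind <- induction(records)
  traj <- trajectory_table(records, stage_order = stages)
  put(traj, "reporter_trajectory.tsv")
  contrasts <- genotype_contrast(
    dplyr::filter(ind, .data$genotype == "knockdown"),
    dplyr::filter(ind, .data$genotype == "control")
  )
  put(contrasts, "reporter_contrasts.tsv")

  ## --- manifest --------------------------------------------------------
  manifest <- list(
    package = "germchrom",
    version = as.character(utils::packageVersion("germchrom")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    parameters = c(
      lapply(unclass(config), function(x) if (length(x) > 1) as.list(x) else x),
      list(
        knockdown_pcg_factor = knockdown_pcg_factor, threshold = threshold,
        spike_norm = spike_norm, alpha = as.list(alphas)
      )
    ),
    inputs = list(
      n_segments = nrow(segments), n_bins = nrow(bins),
      n_genes = nrow(genes), n_reporter_records = nrow(records)
    ),
    files = as.list(unname(vapply(
      files, function(p) unname(tools::md5sum(p)), character(1)
    )) %>% setNames(names(files)))
  )
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote ", length(files) + 1, " files to ", out_dir)

  invisible(list(
    segments = segments, genes = genes, bins = bins,
    enrichment = tables, domain_calls = calls, sharing = sharing,
    chip_fold_change = fc_chip, expression = es, expression_fc = fc,
    reporter = records, trajectory = traj, contrasts = contrasts,
    manifest = manifest, manifest_path = manifest_path
  ))
}
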