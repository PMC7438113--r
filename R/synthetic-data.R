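#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the toy genome, ChIP, expression, and reporter
#' simulators into one validated list. Defaults emulate the study conditions
#' of a germline differentiation experiment: domains tens of kilobases long,
#' a ~10-fold IP rate difference between PcG and background chromatin in
#' differentiated cells, a small constant spike-in admixture (a few thousand
#' foreign cells against half a million target nuclei, i.e. ~1% of reads),
#' overdispersed negative-binomial expression counts, and normally-noised
#' reporter fluorescence.
#'
#' @param n_chromosomes number of target chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param state_mean_length mean chromatin segment length in bases; segment
#'   lengths are geometric (memoryless) with this mean.
#' @param class_weights named probabilities for the four chromatin classes;
#'   must sum to 1.
#' @param enrichment_multipliers named per-class IP rate multipliers
#'   (dimensionless; uniform background corresponds to 1).
#' @param read_length simulated read length in bases.
#' @param ip_depth,input_depth total reads per library (target + spike).
#' @param spike_fraction expected spike-in read fraction of the Input
#'   library, in `[0, 1)`.
#' @param spike_chrom_length length of the dedicated spike chromosome.
#' @param genes_per_class number of genes simulated per chromatin class.
#' @param expression_mean mean baseline expression count per gene.
#' @param expression_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be positive.
#' @param class_log2fc named per-class log2 fold effect applied to
#'   condition B means relative to condition A.
#' @param reporter_background baseline (non-heat-shock) fluorescence, a.u.
#' @param reporter_base_induction fluorescence added by heat shock in the
#'   absence of silencing, a.u.
#' @param silencing_factor multiplicative attenuation of induction in
#'   `(0, 1]`; 1 means no silencing.
#' @param noise_sd fluorescence noise standard deviation, a.u.
#' @param seed master integer seed; all sub-generators derive child seeds
#'   from it via [child_seed()].
#'
#' @return a list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$class_weights
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1e6,
                       state_mean_length = 2e4,
                       class_weights = c(active = 0.45, inactive = 0.35, PcG = 0.10, Hp1 = 0.10),
                       enrichment_multipliers = c(active = 0.2, inactive = 2, PcG = 10, Hp1 = 2),
                       read_length = 75L,
                       ip_depth = 5e5,
                       input_depth = 5e5,
                       spike_fraction = 0.01,
                       spike_chrom_length = 1e5,
                       genes_per_class = 500L,
                       expression_mean = 200,
                       expression_dispersion = 0.05,
                       class_log2fc = c(active = 0, inactive = 0, PcG = 0, Hp1 = 0),
                       reporter_background = 50,
                       reporter_base_induction = 100,
                       silencing_factor = 1,
                       noise_sd = 5,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes), chrom_length = chrom_length,
    state_mean_length = state_mean_length, class_weights = class_weights,
    enrichment_multipliers = enrichment_multipliers,
    read_length = as.integer(read_length),
    ip_depth = ip_depth, input_depth = input_depth,
    spike_fraction = spike_fraction, spike_chrom_length = spike_chrom_length,
    genes_per_class = as.integer(genes_per_class),
    expression_mean = expression_mean,
    expression_dispersion = expression_dispersion,
    class_log2fc = class_log2fc,
    reporter_background = reporter_background,
    reporter_base_induction = reporter_base_induction,
    silencing_factor = silencing_factor, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_chromosomes < 1 || chrom_length <= 0 || state_mean_length <= 0) {
      abort("chromosome counts and lengths must be positive")
    }
    if (!setequal(names(class_weights), CHROMATIN_CLASSES)) {
      abort("class_weights must be named with the four chromatin classes")
    }
    if (any(class_weights < 0) || abs(sum(class_weights) - 1) > 1e-8) {
      abort("class_weights must be non-negative and sum to 1")
    }
    if (!setequal(names(enrichment_multipliers), CHROMATIN_CLASSES) ||
      any(enrichment_multipliers <= 0)) {
      abort("enrichment_multipliers must be positive and cover all four classes")
    }
    if (read_length <= 0 || ip_depth < 0 || input_depth < 0) {
      abort("read_length must be positive and depths non-negative")
    }
    if (spike_fraction < 0 || spike_fraction >= 1) abort("spike_fraction must lie in [0, 1)")
    if (genes_per_class < 0 || expression_mean <= 0) {
      abort("genes_per_class must be non-negative and expression_mean positive")
    }
    if (expression_dispersion <= 0) abort("expression_dispersion must be positive")
    if (silencing_factor <= 0 || silencing_factor > 1) abort("silencing_factor must lie in (0, 1]")
    if (noise_sd < 0) abort("noise_sd must be non-negative")
  })
  invisible(cfg)
}

#' Simulate a four-class chromatin landscape with embedded genes
#'
#' Partitions each chromosome into chromatin segments whose lengths are
#' geometric with mean `state_mean_length` and whose classes are drawn from
#' `class_weights` with the constraint that adjacent segments differ in
#' class. Genes are then placed wholly inside segments of their intended
#' class, with 1-3 isoforms whose common intersection equals the collapsed
#' gene interval.
#'
#' @param config a [sim_config()].
#' @return a list with `segments` (tibble: chrom, start, end, class) that
#'   partition every chromosome, and `genes` (tibble: gene_id, chrom, start,
#'   end, strand, class, length_for_tpm, tss, isoforms list-column).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  if (config$chrom_length < config$state_mean_length) {
    abort("chrom_length must be at least one mean segment length")
  }
  set.seed(child_seed(config$seed, "genome"))

  segments <- purrr::map_dfr(seq_len(config$n_chromosomes), function(i) {
    chrom <- paste0("chr", i)
    L <- config$chrom_length
    ## draw enough geometric lengths to tile the chromosome, then truncate
    lens <- integer(0)
    while (sum(lens) < L) {
      extra <- rgeom(ceiling(L / config$state_mean_length) + 10L,
        prob = 1 / config$state_mean_length
      ) + 1L
      lens <- c(lens, extra)
    }
    ends <- cumsum(as.numeric(lens))
    lens <- lens[seq_len(which(ends >= L)[1])]
    ends <- cumsum(as.numeric(lens))
    ends[length(ends)] <- L
    starts <- c(0, head(ends, -1))
    keep <- ends > starts # truncation can zero the final segment
    starts <- starts[keep]; ends <- ends[keep]

    cls <- character(length(starts))
    cls[1] <- sample(CHROMATIN_CLASSES, 1, prob = config$class_weights)
    for (k in seq_along(cls)[-1]) {
      w <- config$class_weights
      w[cls[k - 1]] <- 0
      cls[k] <- sample(CHROMATIN_CLASSES, 1, prob = w)
    }
    tibble(chrom = chrom, start = starts, end = ends, class = cls)
  })

  genes <- purrr::map_dfr(CHROMATIN_CLASSES, function(cl) {
    segs <- dplyr::filter(segments, .data$class == cl, .data$end - .data$start >= 1000)
    n <- config$genes_per_class
    if (n == 0 || nrow(segs) == 0) {
      return(tibble())
    }
    pick <- sample(nrow(segs), n, replace = TRUE, prob = segs$end - segs$start)
    seg <- segs[pick, ]
    seg_len <- seg$end - seg$start
    glen <- pmin(seg_len, round(runif(n, 500, 3000)))
    gstart <- seg$start + floor(runif(n) * (seg_len - glen + 1))
    gend <- gstart + glen
    strand <- sample(c("+", "-"), n, replace = TRUE)
    isoforms <- purrr::pmap(list(gstart, gend, seg$start, seg$end), function(s, e, lo, hi) {
      n_iso <- sample(1:3, 1)
      if (n_iso == 1) {
        return(tibble(start = s, end = e))
      }
      ## extensions keep every isoform containing [s, e) and their
      ## intersection exactly [s, e): one isoform pins each boundary
      pads_l <- c(0, floor(runif(n_iso - 1, 0, min(500, s - lo) + 1)))
      pads_r <- c(floor(runif(n_iso - 1, 0, min(500, hi - e) + 1)), 0)
      tibble(start = s - pads_l, end = e + pads_r)
    })
    tibble(
      gene_id = sprintf("g_%s_%04d", cl, seq_len(n)),
      chrom = seg$chrom, start = gstart, end = gend, strand = strand,
      class = cl, length_for_tpm = glen,
      tss = ifelse(strand == "+", gstart, gend),
      isoforms = isoforms
    )
  })

  list(segments = segments, genes = genes)
}

#' Simulate a spike-in tagged IP/Input ChIP library pair
#'
#' Input target reads are placed uniformly along the genome; IP target reads
#' are placed with a per-base rate proportional to the class enrichment
#' multiplier of the segment they fall in. Spike-in reads live on a dedicated
#' spike chromosome. The Input spike fraction equals `spike_fraction`; the IP
#' spike fraction is *derived*, not set: the spike read mass is held fixed
#' while the target IP mass scales with the length-weighted mean multiplier
#' m_bar, giving an IP spike fraction f / (f + (1 - f) * m_bar). A genome-wide
#' gain of target signal therefore dilutes the IP spike fraction, which is
#' precisely the signal spike-in normalization exploits.
#'
#' @param segments segment tibble from [generate_genome()].
#' @param config a [sim_config()].
#' @return list with `ip` and `input`, each a tibble
#'   (species, chrom, start, end) with exactly the configured depth.
#' @export
simulate_chip_pair <- function(segments, config) {
  validate_sim_config(config)
  check_intervals(segments, "segments")
  if (nrow(segments) == 0) abort("segments must be non-empty")
  set.seed(child_seed(config$seed, "chip"))

  seg_len <- segments$end - segments$start
  mult <- config$enrichment_multipliers[segments$class]
  m_bar <- sum(seg_len * mult) / sum(seg_len)
  f <- config$spike_fraction

  sample_reads <- function(n_target, n_spike, weights) {
    target <- if (n_target > 0) {
      pick <- sample.int(nrow(segments), n_target, replace = TRUE, prob = weights)
      pos <- segments$start[pick] + floor(runif(n_target) * seg_len[pick])
      tibble(
        species = "target", chrom = segments$chrom[pick],
        start = pos, end = pos + config$read_length
      )
    } else {
      tibble(species = character(), chrom = character(), start = numeric(), end = numeric())
    }
    spike <- if (n_spike > 0) {
      pos <- floor(runif(n_spike) * (config$spike_chrom_length - config$read_length))
      tibble(species = "spike", chrom = "spike_1", start = pos, end = pos + config$read_length)
    } else {
      tibble(species = character(), chrom = character(), start = numeric(), end = numeric())
    }
    bind_rows(target, spike)
  }

  n_spike_input <- round(f * config$input_depth)
  f_ip <- if (f > 0) f / (f + (1 - f) * m_bar) else 0
  n_spike_ip <- round(f_ip * config$ip_depth)

  list(
    ip = sample_reads(config$ip_depth - n_spike_ip, n_spike_ip, seg_len * mult),
    input = sample_reads(config$input_depth - n_spike_input, n_spike_input, seg_len)
  )
}

#' Simulate a gene-by-sample count matrix with class-dependent fold effects
#'
#' Baseline per-gene means are log-normal around `expression_mean`; counts
#' are negative binomial with dispersion `expression_dispersion`. Condition B
#' means are the condition A means multiplied by `2^class_log2fc` for the
#' gene's chromatin class.
#'
#' @param genes gene tibble (needs `gene_id`, `class`, `length_for_tpm`).
#' @param config a [sim_config()].
#' @param n_reps_per_condition replicates per condition (>= 2).
#' @return an `expr_set`: list with `counts` (matrix), `genes`, `samples`.
#' @export
simulate_expression <- function(genes, config, n_reps_per_condition = 3L) {
  validate_sim_config(config)
  if (n_reps_per_condition < 2) abort("need at least 2 replicates per condition")
  if (!all(genes$class %in% CHROMATIN_CLASSES)) abort("unknown gene class")
  set.seed(child_seed(config$seed, "expression"))

  n <- nrow(genes)
  mu_a <- stats::rlnorm(n, meanlog = log(config$expression_mean), sdlog = 1)
  lfc <- config$class_log2fc[genes$class]
  mu_b <- mu_a * 2^lfc
  size <- 1 / config$expression_dispersion

  draw <- function(mu, nrep) {
    matrix(rnbinom(n * nrep, mu = rep(mu, nrep), size = size), nrow = n)
  }
  counts <- cbind(draw(mu_a, n_reps_per_condition), draw(mu_b, n_reps_per_condition))
  samples <- tibble(
    sample_id = c(
      paste0("A_", seq_len(n_reps_per_condition)),
      paste0("B_", seq_len(n_reps_per_condition))
    ),
    condition = rep(c("A", "B"), each = n_reps_per_condition)
  )
  dimnames(counts) <- list(genes$gene_id, samples$sample_id)
  structure(
    list(counts = counts, genes = dplyr::select(genes, -dplyr::any_of("isoforms")), samples = samples),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat(
    "<expr_set> ", nrow(x$counts), " genes x ", ncol(x$counts), " samples (",
    paste(unique(x$samples$condition), collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate per-cell reporter fluorescence records
#'
#' Non-heat-shocked intensities are Normal(background, noise_sd);
#' heat-shocked intensities are Normal(background + base_induction *
#' silencing_factor, noise_sd), truncated at zero. The silencing factor can
#' vary by line, stage, and genotype through the `silencing` table,
#' emulating silencing that appears only in certain chromatin contexts or
#' developmental stages.
#'
#' @param lines character vector of reporter line ids.
#' @param stages ordered character vector of developmental stages.
#' @param genotypes character vector of genotype labels.
#' @param config a [sim_config()]; `silencing_factor` is the default factor.
#' @param n_reps heat-shocked replicates (ovary pairs) per cell; must be
#'   >= 3.
#' @param n_reps_nohs non-heat-shocked (baseline) replicates per cell;
#'   defaults to `n_reps`. The induction baseline is estimated from these,
#'   so calibration studies of downstream tests may want it larger.
#' @param silencing optional tibble (line_id, stage, genotype,
#'   silencing_factor) overriding the scalar default per cell.
#' @return tibble (line_id, stage, genotype, heat_shock, replicate_id,
#'   intensity).
#' @export
simulate_reporter <- function(lines, stages, genotypes, config, n_reps = 6L,
                              n_reps_nohs = n_reps, silencing = NULL) {
  validate_sim_config(config)
  if (n_reps < 3 || n_reps_nohs < 3) abort("need at least 3 replicates per cell")
  set.seed(child_seed(config$seed, "reporter"))

  grid <- tidyr::expand_grid(
    line_id = lines, stage = stages, genotype = genotypes,
    heat_shock = c(FALSE, TRUE), replicate_id = seq_len(max(n_reps, n_reps_nohs))
  ) %>%
    dplyr::filter(.data$replicate_id <= ifelse(.data$heat_shock, n_reps, n_reps_nohs))
  if (!is.null(silencing)) {
    grid <- left_join(grid, silencing, by = c("line_id", "stage", "genotype"))
    grid$silencing_factor[is.na(grid$silencing_factor)] <- config$silencing_factor
  } else {
    grid$silencing_factor <- config$silencing_factor
  }
  mu <- config$reporter_background +
    ifelse(grid$heat_shock, config$reporter_base_induction * grid$silencing_factor, 0)
  grid$intensity <- pmax(0, rnorm(nrow(grid), mean = mu, sd = config$noise_sd))
  grid$stage <- factor(grid$stage, levels = stages, ordered = TRUE)
  dplyr::select(grid, -"silencing_factor")
}
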