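make_lib <- function(reads, role = "IP") chip_library(reads, paste0("t_", role), role)

test_that("midpoint counting over overlapping bins matches brute force", {
  bins <- make_bins(tibble::tibble(chrom = "chr1", length = 30000))
  ## a single read with midpoint 2600 hits the 6 bins starting 0..2500
  one <- tibble::tibble(species = "target", chrom = "chr1", start = 2563, end = 2638)
  counts <- count_reads_per_bin(make_lib(one), bins)
  expect_equal(sum(counts), 6)
  expect_equal(bins$start[counts == 1], seq(0, 2500, 500))

  ## zero reads and spike-only reads give all-zero counts
  expect_equal(sum(count_reads_per_bin(make_lib(one[0, ]), bins)), 0)
  spike <- tibble::tibble(species = "spike", chrom = "chr1", start = 100, end = 175)
  expect_equal(sum(count_reads_per_bin(make_lib(spike), bins)), 0)

  ## property: random reads vs O(n*m) oracle
  set.seed(3)
  rs <- sample(0:29000, 200)
  reads <- tibble::tibble(
    species = sample(c("target", "spike"), 200, replace = TRUE),
    chrom = "chr1", start = rs, end = rs + 75
  )
  got <- count_reads_per_bin(make_lib(reads), bins)
  want <- vapply(
    seq_len(nrow(bins)),
    function(i) oracle_count_midpoints(reads, bins$start[i], bins$end[i], "chr1"),
    integer(1)
  )
  expect_equal(got, want)
})

test_that("RPM scaling is linear in counts and guards the total", {
  expect_equal(rpm_scale(10, 1e6), 10)
  expect_equal(rpm_scale(0, 123), 0)
  expect_equal(rpm_scale(37, 2e6), 18.5)
  expect_error(rpm_scale(1, 0), "positive")
})

test_that("spike normalization factor follows the input/IP spike proportion ratio", {
  lib <- function(n_target, n_spike, role) {
    reads <- dplyr::bind_rows(
      tibble::tibble(
        species = rep("target", n_target), chrom = "chr1",
        start = seq_len(n_target), end = seq_len(n_target) + 75
      ),
      tibble::tibble(
        species = rep("spike", n_spike), chrom = "spike_1",
        start = seq_len(n_spike), end = seq_len(n_spike) + 75
      )
    )
    chip_library(reads, role, role)
  }
  ## equal spike fractions: identity
  expect_equal(spike_normalization_factor(lib(90, 10, "IP"), lib(90, 10, "Input")), 1)
  ## input fraction 0.10, IP fraction 0.05: alpha = 2
  expect_equal(spike_normalization_factor(lib(95, 5, "IP"), lib(90, 10, "Input")), 2)
  expect_error(
    spike_normalization_factor(lib(100, 0, "IP"), lib(90, 10, "Input")),
    "spike"
  )
})

test_that("alpha is invariant under library subsampling in expectation", {
  cfg <- sim_config(
    n_chromosomes = 1L, chrom_length = 4e5, ip_depth = 2e5,
    input_depth = 2e5, spike_fraction = 0.05, seed = 13
  )
  seg <- generate_genome(cfg)$segments
  libs <- simulate_chip_pair(seg, cfg)
  full <- spike_normalization_factor(
    make_lib(libs$ip), make_lib(libs$input, "Input")
  )
  set.seed(99)
  halves <- replicate(20, {
    spike_normalization_factor(
      make_lib(dplyr::slice_sample(libs$ip, prop = 0.5)),
      make_lib(dplyr::slice_sample(libs$input, prop = 0.5), "Input")
    )
  })
  expect_equal(mean(halves), full, tolerance = 0.02)
})

test_that("bin enrichment arithmetic and global conservation hold", {
  bins <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(5000, 5500))
  same <- bin_enrichment(bins, c(3, 7), c(3, 7), alpha = 1)
  expect_equal(same$enrichment, c(1, 1))
  expect_equal(bin_enrichment(bins, c(20, 20), c(2, 2))$enrichment, c(10, 10))
  expect_error(bin_enrichment(bins, 1, c(1, 2)), "row for row")

  ## with alpha = 1 and epsilon = 0 the input-RPM-weighted mean of E is 1
  ## when both tracks are computed over the same bin universe
  set.seed(8)
  ip_rpm <- runif(50, 0.1, 10)
  input_rpm <- runif(50, 0.1, 10)
  tab <- bin_enrichment(
    tibble::tibble(chrom = "c", start = 0:49 * 100, end = 0:49 * 100 + 100),
    ip_rpm * sum(input_rpm) / sum(ip_rpm), input_rpm,
    alpha = 1, epsilon = 0
  )
  expect_equal(sum(tab$enrichment * tab$input_rpm) / sum(tab$input_rpm), 1)
})

test_that("per-class enrichment recovers the configured multiplier ratios", {
  cfg <- sim_config(seed = 21, ip_depth = 2e5, input_depth = 2e5)
  g <- generate_genome(cfg)
  libs <- simulate_chip_pair(g$segments, cfg)
  bins <- make_bins(
    dplyr::summarise(dplyr::group_by(g$segments, chrom), length = max(end))
  )
  bins <- assign_bin_class(bins, g$segments)
  tab <- enrichment_table(make_lib(libs$ip), make_lib(libs$input, "Input"), bins)
  med <- tapply(tab$enrichment[tab$class != "mixed"], tab$class[tab$class != "mixed"], median)
  m <- cfg$enrichment_multipliers
  ## ratio form is exact at any spike fraction
  expect_equal(med[["PcG"]] / med[["inactive"]], m[["PcG"]] / m[["inactive"]],
    tolerance = 0.1
  )
  expect_equal(med[["active"]] / med[["inactive"]], m[["active"]] / m[["inactive"]],
    tolerance = 0.1
  )
})

test_that("a global doubling of target IP signal doubles spike-normalized enrichment", {
  base <- sim_config(
    n_chromosomes = 1L, chrom_length = 5e5, ip_depth = 2e5,
    input_depth = 2e5, spike_fraction = 0.05, seed = 17
  )
  doubled <- base
  doubled$enrichment_multipliers <- base$enrichment_multipliers * 2
  seg <- generate_genome(base)$segments
  bins <- assign_bin_class(
    make_bins(tibble::tibble(chrom = "chr1", length = 5e5)), seg
  )
  mean_e <- function(cfg) {
    libs <- simulate_chip_pair(seg, cfg)
    tab <- enrichment_table(make_lib(libs$ip), make_lib(libs$input, "Input"), bins)
    mean(tab$enrichment[tab$class != "mixed"])
  }
  expect_equal(mean_e(doubled) / mean_e(base), 2, tolerance = 0.05)
})

test_that("class densities are proportion-normalized within each class", {
  bins <- tibble::tibble(
    chrom = "c", start = 0:199 * 500, end = 0:199 * 500 + 5000,
    class = rep(c("active", "PcG"), each = 100)
  )
  set.seed(5)
  tab <- bin_enrichment(bins, c(runif(100, 1, 2), runif(100, 40, 80)), rep(1, 200))
  d <- class_density(tab, c("active", "PcG"))
  for (cl in c("active", "PcG")) {
    dd <- d[d$class == cl, ]
    area <- sum(diff(dd$log2_enrichment) * (head(dd$density, -1) + tail(dd$density, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-3) # trapezoid quadrature
  }
  ## disjoint enrichment ranges give non-overlapping supports
  expect_lt(
    max(d$log2_enrichment[d$class == "active" & d$density > 1e-6]),
    min(d$log2_enrichment[d$class == "PcG" & d$density > 1e-6])
  )
  expect_warning(class_density(tab, c("active", "Hp1")), "Hp1")
})

test_that("domain calls threshold mean enrichment and sharing matches set algebra", {
  domains <- tibble::tibble(
    chrom = "c", start = c(0, 20000), end = c(15000, 40000),
    class = c("PcG", "PcG")
  )
  bins <- tibble::tibble(
    chrom = "c", start = c(2000, 7000, 22000, 30000),
    end = c(7000, 12000, 27000, 35000),
    class = c("PcG", "PcG", "PcG", "mixed")
  )
  tab <- bin_enrichment(bins, c(10, 10, 1, 50), rep(1, 4))
  calls <- call_domains(domains, tab, threshold = 2)
  expect_equal(calls$enriched, c(TRUE, FALSE)) # mixed bin never counts
  expect_equal(calls$mean_enrichment, c(10, 1))

  ## a domain below min_size is dropped; one with no usable bins is NA
  small <- tibble::tibble(chrom = "c", start = 0, end = 5000, class = "PcG")
  expect_equal(nrow(call_domains(small, tab)), 0)
  bare <- tibble::tibble(chrom = "c", start = 50000, end = 70000, class = "PcG")
  expect_true(is.na(call_domains(bare, tab)$enriched))

  ## sharing: three samples enriching the same 5 domains -> 100% shared
  all5 <- matrix(TRUE, nrow = 5, ncol = 3)
  s <- share_domains(all5)
  expect_equal(s$n_shared_all, 5)
  expect_equal(s$n_union, 5)
  expect_equal(s$pct_shared, 100)

  ## random boolean matrices vs a set-algebra oracle
  set.seed(11)
  for (i in 1:10) {
    mat <- matrix(sample(c(TRUE, FALSE), 60, replace = TRUE), ncol = 3)
    s <- share_domains(mat)
    sets <- apply(mat, 2, which, simplify = FALSE)
    expect_equal(s$n_shared_all, length(Reduce(intersect, sets)))
    expect_equal(s$n_union, length(Reduce(union, sets)))
  }
})

test_that("fold-change summaries are zero on identity and notch scales as 1/sqrt(n)", {
  n <- 400
  bins <- tibble::tibble(
    chrom = "c", start = 0:(n - 1) * 500, end = 0:(n - 1) * 500 + 5000,
    class = rep(c("inactive", "PcG"), each = n / 2),
    pre_flag = rep(c(FALSE, TRUE), n / 2)
  )
  set.seed(2)
  e <- runif(n, 1, 10)
  ta <- bin_enrichment(bins, e, rep(1, n))
  fc0 <- fold_change_summary(ta, ta)
  expect_true(all(fc0$summary$median == 0))

  ## notch = 1.58 IQR / sqrt(n): quadrupling n at fixed IQR halves it
  x <- rep(c(1, 2, 3, 4), 25) # fixed quartiles
  mk <- function(k) {
    b <- tibble::tibble(
      chrom = "c", start = seq_len(100 * k) * 500,
      end = seq_len(100 * k) * 500 + 5000, class = "inactive"
    )
    ea <- bin_enrichment(b, 2^rep(x, k), rep(1, 100 * k))
    eb <- bin_enrichment(b, rep(1, 100 * k), rep(1, 100 * k))
    fold_change_summary(ea, eb, classes = "inactive")$summary$notch
  }
  expect_equal(mk(4) / mk(1), 0.5, tolerance = 0.01)
  expect_error(fold_change_summary(ta, ta[1:10, ]), "identical bin")
})

test_that("simulated PcG-specific knockdown shows up only in PcG-bin fold changes", {
  ctrl <- sim_config(
    n_chromosomes = 1L, chrom_length = 5e5, ip_depth = 2e5,
    input_depth = 2e5, seed = 19
  )
  kd <- ctrl
  kd$enrichment_multipliers["PcG"] <- kd$enrichment_multipliers["PcG"] / 2
  seg <- generate_genome(ctrl)$segments
  bins <- assign_bin_class(
    make_bins(tibble::tibble(chrom = "chr1", length = 5e5)), seg
  )
  tab_for <- function(cfg) {
    libs <- simulate_chip_pair(seg, cfg)
    enrichment_table(make_lib(libs$ip), make_lib(libs$input, "Input"), bins)
  }
  fc <- fold_change_summary(tab_for(kd), tab_for(ctrl), classes = c("inactive", "PcG"))
  s <- fc$summary
  expect_equal(s$median[s$class == "PcG"], -1, tolerance = 0.15)
  expect_equal(s$median[s$class == "inactive"], 0, tolerance = 0.15)
})

test_that("peak matrices center summits, pad chromosome ends, and match brute force", {
  sizes <- tibble::tibble(chrom = "chr1", length = 100000)
  summits <- tibble::tibble(chrom = "chr1", pos = c(50000, 3000))
  ## one read exactly at a summit: maximal center column
  at <- tibble::tibble(species = "target", chrom = "chr1", start = 49963, end = 50038)
  m <- peak_matrix(make_lib(at), summits, sizes, window = 20000, binsize = 500)
  expect_equal(unname(m[1, "0"]), 1)
  expect_equal(sum(m[1, ], na.rm = TRUE), 1)
  ## summit 3000 is closer than 10 kb to the start: leading cells NA
  expect_true(any(is.na(m[2, ])))
  expect_equal(sum(is.na(m[2, ])), (10000 - 3000) / 500)

  ## empty library: all-zero (or NA) matrix
  m0 <- peak_matrix(make_lib(at[0, ]), summits, sizes)
  expect_equal(sum(m0, na.rm = TRUE), 0)

  ## row sums equal brute-force counting in each +/- 10 kb window
  set.seed(6)
  rs <- sample(0:99000, 500)
  reads <- tibble::tibble(species = "target", chrom = "chr1", start = rs, end = rs + 75)
  mm <- peak_matrix(make_lib(reads), summits, sizes, order_rows = FALSE)
  for (i in 1:2) {
    lo <- summits$pos[i] - 10000
    expect_equal(
      sum(mm[i, ], na.rm = TRUE),
      oracle_count_midpoints(reads, max(lo, 0), min(summits$pos[i] + 10000, 1e5), "chr1")
    )
  }
})

test_that("TSS windows are strand-aware and agree with direct recomputation", {
  sizes <- tibble::tibble(chrom = "chr1", length = 50000)
  set.seed(14)
  rs <- sample(0:49900, 3000)
  ip <- make_lib(tibble::tibble(species = "target", chrom = "chr1", start = rs, end = rs + 75))
  rs2 <- sample(0:49900, 3000)
  inp <- make_lib(
    tibble::tibble(species = "target", chrom = "chr1", start = rs2, end = rs2 + 75), "Input"
  )
  tss <- tibble::tibble(
    gene_id = c("plus", "minus", "edge"),
    chrom = "chr1", pos = c(10000, 10000, 49800), strand = c("+", "-", "+")
  )
  got <- tss_window_enrichment(ip, inp, tss, sizes, spike_norm = FALSE, epsilon = 1)
  expect_equal(got$start, c(10000, 9500, 49800))
  expect_equal(got$end, c(10500, 10000, 50300))
  expect_true(got$out_of_range[3] && is.na(got$enrichment[3]))

  ## oracle: direct midpoint counting + RPM + pseudocount arithmetic
  win_e <- function(s, e) {
    ipc <- oracle_count_midpoints(ip$reads, s, e, "chr1")
    inc <- oracle_count_midpoints(inp$reads, s, e, "chr1")
    (ipc * 1e6 / 3000 + 1) / (inc * 1e6 / 3000 + 1)
  }
  expect_equal(got$enrichment[1], win_e(10000, 10500))
  expect_equal(got$enrichment[2], win_e(9500, 10000))
})
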