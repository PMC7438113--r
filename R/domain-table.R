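#' Curated PcG domain table (differing domains across three cell types)
#'
#' The shipped table lists the annotated PcG domains whose enrichment state
#' differs between nurse cells, follicle cells, and S2 cells, with their
#' coordinate spans (`ARM:START..END`) and the per-cell-type chromatin
#' state. Domains carrying `PcG` in a state string are H3K27me3-enriched in
#' that cell type.
#'
#' @return tibble (name, coords, length_kb, nc_state, fc_state, s2_state).
#' @export
pcg_domain_table <- function() {
  read_tsv_commented(
    system.file("extdata", "pcg_domain_table.tsv", package = "germchrom")
  )
}

#' Three-way enrichment call matrix from a differing-domain table
#'
#' Reconstructs the full boolean domain x cell-type call matrix behind a
#' cross-cell-type sharing summary: `n_background` domains enriched in all
#' cell types, plus one row per listed differing domain, enriched wherever
#' its state string contains `PcG`. Feed the result to [share_domains()].
#'
#' @param table a tibble shaped like [pcg_domain_table()].
#' @param n_background number of domains enriched in every cell type.
#' @return logical matrix with columns nurse, follicle, s2.
#' @export
three_way_domain_calls <- function(table = pcg_domain_table(),
                                   n_background = 111) {
  listed <- cbind(
    nurse = grepl("PcG", table$nc_state, ignore.case = TRUE),
    follicle = grepl("PcG", table$fc_state, ignore.case = TRUE),
    s2 = grepl("PcG", table$s2_state, ignore.case = TRUE)
  )
  background <- matrix(TRUE, nrow = n_background, ncol = 3,
    dimnames = list(NULL, colnames(listed))
  )
  rbind(background, listed)
}
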