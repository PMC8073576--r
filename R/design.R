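#' Build the bait-pulldown experiment design
#'
#' One sample per (isoform, genotype, replicate) triple: each peroxiredoxin
#' isoform bait is pulled down as wild type (`WT`), resolving-cysteine mutant
#' (`CRS`) and catalytic-dead double mutant (`CPRS`), in biological
#' replicates.
#'
#' @param isoforms Character vector of bait isoforms.
#' @param genotypes Character vector of bait genotypes.
#' @param n_replicates Biological replicates per (isoform, genotype) cell.
#' @return A tibble with columns `sample_id`, `isoform`, `genotype`,
#'   `replicate` and `condition` (the `isoform_genotype` cell label).
#' @examples
#' prdx_design(isoforms = c("PRDX1", "PRDX3"), n_replicates = 3)
#' @export
prdx_design <- function(isoforms = PRDX_ISOFORMS,
                        genotypes = GENOTYPES,
                        n_replicates = 3L) {
  if (n_replicates < 2) {
    abort("`n_replicates` must be at least 2 for every modeled condition.")
  }
  out <- tidyr::expand_grid(
    isoform = isoforms,
    genotype = genotypes,
    replicate = seq_len(n_replicates)
  )
  out |>
    mutate(
      sample_id = paste(.data$isoform, .data$genotype, .data$replicate,
                        sep = "_"),
      condition = paste(.data$isoform, .data$genotype, sep = "_")
    ) |>
    select("sample_id", "isoform", "genotype", "replicate", "condition")
}
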