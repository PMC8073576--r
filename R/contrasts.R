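# Orchestrated contrasts: per-isoform genotype comparisons and
# isoform-vs-all-other-isoforms comparisons.

#' Per-isoform genotype contrasts
#'
#' For each isoform, fits the dropout model to that isoform's samples of the
#' two genotypes and tests `genotypes[1]` vs `genotypes[2]` (positive delta
#' = enriched with the first genotype's bait). The default `WT` vs `CPRS`
#' comparison defines cysteine-dependent binding; `CRS` vs `CPRS` defines
#' peroxidatic-cysteine-dependent binding; `WT` vs `CRS` probes the
#' resolving-cysteine requirement.
#'
#' @param lfq Long log2-scale LFQ tibble (filtered, normalized).
#' @param design Experiment design.
#' @param genotypes Length-2 character vector of genotypes to compare.
#' @param curves Optional dropout curves (estimated on the full design when
#'   `NULL`, then reused for every isoform subset).
#' @param min_obs Keep only proteins observed in at least this many of the
#'   subset's samples (proteins never seen with an isoform's baits carry no
#'   information about it).
#' @return Tibble of per-protein contrast results with an `isoform` column;
#'   BH adjustment is within isoform.
#' @export
genotype_contrasts <- function(lfq, design,
                               genotypes = c("WT", "CPRS"),
                               curves = NULL,
                               min_obs = 1L) {
  check_lfq(lfq)
  check_design(design)
  if (length(genotypes) != 2 || genotypes[1] == genotypes[2]) {
    abort("`genotypes` must be two distinct genotype labels.")
  }
  curves <- curves %||% estimate_dropout_curves(lfq, design)
  isoforms <- unique(design$isoform)
  purrr::map_dfr(isoforms, function(iso) {
    sub_design <- design |>
      filter(.data$isoform == iso, .data$genotype %in% genotypes) |>
      mutate(condition = .data$genotype)
    if (length(unique(sub_design$genotype)) < 2) {
      return(NULL)
    }
    sub_lfq <- lfq |>
      filter(.data$sample_id %in% sub_design$sample_id)
    keep <- sub_lfq |>
      summarise(n = sum(!is.na(.data$intensity)), .by = "protein_id") |>
      filter(.data$n >= min_obs)
    sub_lfq <- set_lfq_scale(
      sub_lfq |> filter(.data$protein_id %in% keep$protein_id),
      lfq_scale(lfq)
    )
    if (nrow(sub_lfq) == 0) {
      return(NULL)
    }
    fit <- fit_dropout_model(sub_lfq, sub_design,
                             curves = curves[curves$sample_id %in%
                                               sub_design$sample_id, ])
    test_contrast(fit, genotypes) |>
      mutate(isoform = iso, .before = 1)
  })
}

#' Isoform-vs-rest contrasts
#'
#' For each isoform, compares all of its bait samples (every genotype)
#' against all samples of the other isoforms, asking which proteins are
#' enriched with that isoform irrespective of cysteine dependency.
#'
#' @inheritParams genotype_contrasts
#' @return Tibble of per-protein contrast results with an `isoform` column
#'   (`delta` > 0 = enriched with this isoform); BH adjustment within
#'   isoform.
#' @export
isoform_specificity_contrasts <- function(lfq, design, curves = NULL,
                                          min_obs = 1L) {
  check_lfq(lfq)
  check_design(design)
  curves <- curves %||% estimate_dropout_curves(lfq, design)
  isoforms <- unique(design$isoform)
  if (length(isoforms) < 2) {
    abort("Isoform specificity needs at least two isoforms in the design.")
  }
  purrr::map_dfr(isoforms, function(iso) {
    sub_design <- design |>
      mutate(condition = ifelse(.data$isoform == iso, "target", "rest"))
    fit <- fit_dropout_model(lfq, sub_design, curves = curves)
    test_contrast(fit, c("target", "rest")) |>
      mutate(isoform = iso, .before = 1)
  })
}
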