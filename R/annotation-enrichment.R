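# Overlap with a redox-sensitivity reference and compartment enrichment.

#' Overlap of interactor sets with a redox-sensitivity reference
#'
#' For each set, the percentage of members previously reported as
#' redox-sensitive, next to the same percentage in the full protein universe
#' (the baseline), and their ratio.
#'
#' @param sets Named list of id vectors (or tibbles with `protein_id`); an
#'   `"overall"` row for the union is added.
#' @param reference_ids Character ids of the redox-sensitive reference.
#' @param universe_ids All ids the sets are drawn from.
#' @return Tibble with `set`, `n`, `n_in_reference`, `pct` (`NA` for empty
#'   sets), `background_pct`, `fold`.
#' @export
redox_overlap <- function(sets, reference_ids, universe_ids) {
  sets <- lapply(sets, function(x) {
    if (is.data.frame(x)) unique(x$protein_id) else unique(as.character(x))
  })
  outside <- setdiff(unique(unlist(sets)), universe_ids)
  if (length(outside) > 0) {
    abort(sprintf("Set members outside the universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  reference_ids <- unique(reference_ids)
  bg_pct <- 100 * mean(universe_ids %in% reference_ids)
  all_sets <- c(sets, list(overall = unique(unlist(sets))))
  purrr::imap_dfr(all_sets, function(ids, nm) {
    n <- length(ids)
    n_ref <- sum(ids %in% reference_ids)
    pct <- if (n == 0) NA_real_ else 100 * n_ref / n
    tibble(
      set = nm, n = n, n_in_reference = n_ref, pct = pct,
      background_pct = bg_pct,
      fold = if (bg_pct == 0) NA_real_ else pct / bg_pct
    )
  })
}

#' Compartment enrichment of top interactors
#'
#' Selects, per isoform, the interactors with the strongest binding
#' (`delta > log2(fold_min)`, i.e. more than `fold_min`-fold enriched on the
#' WT-vs-catalytic-dead contrast), and compares their compartment
#' distribution with the full annotation table: fold enrichment =
#' fraction among selected / fraction in the background table. Compartments
#' absent among the selected get fold 0; compartments absent from the
#' background get `NA` (undefined). Selected ids without annotation are
#' counted as missing.
#'
#' @param classified Tibble of classified interactors with `isoform`,
#'   `protein_id`, `delta` (e.g. [classify_cysteine_dependent()] output).
#' @param compartment_table Tibble with `protein_id`, `compartment` (one
#'   compartment per protein).
#' @param fold_min Minimum raw fold change for the "top binder" selection.
#' @return Tibble with one row per (isoform, compartment): `n_selected`,
#'   `frac_selected`, `frac_background`, `fold_enrichment`, plus the
#'   per-isoform `n_top` and `n_unannotated` bookkeeping columns.
#' @export
localization_enrichment <- function(classified, compartment_table,
                                    fold_min = 10) {
  if (fold_min <= 0) {
    abort("`fold_min` must be positive.")
  }
  if (anyDuplicated(compartment_table$protein_id)) {
    abort("`compartment_table` must have one compartment per protein.")
  }
  compartments <- unique(compartment_table$compartment)
  bg <- compartment_table |>
    count(.data$compartment, name = "n_bg") |>
    mutate(frac_background = .data$n_bg / sum(.data$n_bg))

  top <- classified |>
    filter(.data$delta > log2(fold_min))
  if (nrow(top) == 0) {
    warn("No interactors above the fold-change selection; empty result.")
    return(tibble(
      isoform = character(), compartment = character(),
      n_selected = integer(), frac_selected = double(),
      frac_background = double(), fold_enrichment = double(),
      n_top = integer(), n_unannotated = integer()
    ))
  }
  top |>
    left_join(compartment_table, by = "protein_id") |>
    summarise(
      n_top = n(),
      n_unannotated = sum(is.na(.data$compartment)),
      counts = list(table(factor(.data$compartment, levels = compartments))),
      .by = "isoform"
    ) |>
    mutate(compartment = list(compartments)) |>
    tidyr::unnest_longer(col = c("compartment")) |>
    mutate(n_selected = purrr::map2_int(.data$counts, .data$compartment,
                                        ~ as.integer(.x[[.y]]))) |>
    select(-"counts") |>
    mutate(frac_selected = .data$n_selected / .data$n_top) |>
    left_join(bg[, c("compartment", "frac_background")], by = "compartment") |>
    mutate(fold_enrichment = ifelse(
      is.na(.data$frac_background) | .data$frac_background == 0,
      NA_real_, .data$frac_selected / .data$frac_background
    )) |>
    select("isoform", "compartment", "n_selected", "frac_selected",
           "frac_background", "fold_enrichment", "n_top", "n_unannotated")
}
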