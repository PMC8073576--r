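# Turning contrast tables into interactor classifications and set algebra.

p_column <- function(p_mode) {
  p_mode <- match.arg(tolower(p_mode), c("raw", "bh"))
  if (p_mode == "raw") "p" else "q"
}

#' Classify cysteine-dependent interactors
#'
#' Proteins enriched with the wild-type bait over the catalytic-dead mutant:
#' `delta > delta_min` and (raw or BH-adjusted) p below `alpha`. Only
#' positive `delta` (WT-enriched) counts as binding.
#'
#' @param contrasts Contrast tibble (e.g. from [genotype_contrasts()] with
#'   `WT` vs `CPRS`), with columns `delta`, `p`, `q` and optionally
#'   `isoform`.
#' @param delta_min Log2 fold-change gate (>= 0; default 1, i.e. two-fold).
#' @param alpha Significance gate.
#' @param p_mode `"raw"` or `"bh"`: which p-value the gate uses.
#' @return The passing rows of `contrasts` (tibble).
#' @export
classify_cysteine_dependent <- function(contrasts, delta_min = 1,
                                        alpha = 0.05, p_mode = "raw") {
  if (delta_min < 0) {
    abort("`delta_min` must be non-negative.")
  }
  pc <- p_column(p_mode)
  contrasts |>
    filter(.data$delta > delta_min, .data[[pc]] < alpha)
}

#' Classify isoform-specific interactors
#'
#' Same gates applied to the isoform-vs-all-other-isoforms contrast
#' (BH-adjusted p by default, matching how multi-isoform comparisons are
#' usually reported).
#'
#' @param contrasts Contrast tibble from [isoform_specificity_contrasts()].
#' @inheritParams classify_cysteine_dependent
#' @return The passing rows of `contrasts` (tibble, per isoform).
#' @export
classify_isoform_specific <- function(contrasts, delta_min = 1,
                                      alpha = 0.05, p_mode = "bh") {
  classify_cysteine_dependent(contrasts, delta_min = delta_min,
                              alpha = alpha, p_mode = p_mode)
}

#' Split interactors into SOH and disulfide-relay mechanisms
#'
#' Cysteine-dependent interactors of the wild-type bait that also bind the
#' resolving-cysteine mutant can start their disulfide from the sulfenylated
#' peroxidatic cysteine (`SOH`); those lost with the resolving-cysteine
#' mutant require the catalytic disulfide relay (`SS`). Proteins binding
#' the resolving-cysteine mutant only are excluded from the split and
#' reported separately.
#'
#' @param wt_set Character ids (or a tibble with `protein_id`) of wild-type
#'   cysteine-dependent interactors.
#' @param crs_set Ids binding the resolving-cysteine mutant bait
#'   (CRS vs catalytic-dead contrast).
#' @return List of class `prx_mechanism`: `assignments` (tibble
#'   `protein_id`, `mechanism`), `crs_only` ids, `n_soh`, `n_ss`, `ss_pct`
#'   (percentage of the wild-type set on the relay mechanism).
#' @export
classify_mechanism <- function(wt_set, crs_set) {
  ids <- function(x) {
    if (is.data.frame(x)) unique(x$protein_id) else unique(as.character(x))
  }
  wt <- ids(wt_set)
  crs <- ids(crs_set)
  soh <- intersect(wt, crs)
  ss <- setdiff(wt, crs)
  assignments <- tibble(
    protein_id = c(soh, ss),
    mechanism = rep(c("SOH", "SS"), c(length(soh), length(ss)))
  )
  structure(
    list(
      assignments = assignments,
      crs_only = setdiff(crs, wt),
      n_soh = length(soh),
      n_ss = length(ss),
      ss_pct = if (length(wt) == 0) NA_real_ else 100 * length(ss) / length(wt)
    ),
    class = "prx_mechanism"
  )
}

#' @export
print.prx_mechanism <- function(x, ...) {
  cat(sprintf(
    "<prx_mechanism> SOH: %d, SS: %d (%.1f%% relay), CRS-only excluded: %d\n",
    x$n_soh, x$n_ss, x$ss_pct %||% NA_real_, length(x$crs_only)
  ))
  invisible(x)
}

#' Exclusive set intersections (UpSet-style)
#'
#' Counts, for every non-empty membership pattern over the given sets, the
#' ids belonging to exactly that combination of sets. Counts over exclusive
#' patterns sum to the size of the union.
#'
#' @param sets Named list of character id vectors (or tibbles with
#'   `protein_id`).
#' @return Tibble with `pattern` (set names joined by `&`), `sets` (list
#'   column), `degree`, `n` and `proteins` (list column), sorted by
#'   decreasing `n`.
#' @export
set_intersections <- function(sets) {
  if (length(sets) == 0 || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a non-empty named list.")
  }
  sets <- lapply(sets, function(x) {
    if (is.data.frame(x)) unique(x$protein_id) else unique(as.character(x))
  })
  universe <- unique(unlist(sets))
  if (length(universe) == 0) {
    return(tibble(pattern = character(), sets = list(), degree = integer(),
                  n = integer(), proteins = list()))
  }
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) {
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(NULL, names(sets)))
  }
  key <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  split_ids <- split(universe, key)
  tibble(
    pattern = names(split_ids),
    sets = strsplit(names(split_ids), "&", fixed = TRUE),
    degree = unname(lengths(strsplit(names(split_ids), "&", fixed = TRUE))),
    n = unname(lengths(split_ids)),
    proteins = unname(split_ids)
  ) |>
    arrange(desc(.data$n), .data$pattern)
}

#' Pairwise overlap matrix between sets
#'
#' @param sets Named list of id vectors.
#' @return Symmetric integer matrix of pairwise intersection sizes
#'   (diagonal = set sizes), for Venn-style reporting.
#' @export
pairwise_overlap <- function(sets) {
  sets <- lapply(sets, function(x) {
    if (is.data.frame(x)) unique(x$protein_id) else unique(as.character(x))
  })
  k <- length(sets)
  out <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  out
}
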