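# proteinGroups-dialect I/O, FASTA, reference lists, and the protein filters.

#' Write a proteinGroups-dialect table
#'
#' Serializes a simulated (or assembled) experiment in the MaxQuant
#' proteinGroups dialect: one row per protein group, one
#' `LFQ intensity <sample>` column per sample, `0` for not-quantified cells,
#' `+` flags in `Reverse` / `Potential contaminant`.
#'
#' @param proteins Record table with `protein_id`, `gene_name`,
#'   `n_unique_peptides`, `reverse`, `contaminant`.
#' @param lfq Long LFQ tibble. Log2-scale tables are written back on the raw
#'   scale (`2^value`), matching the file convention.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(proteins, lfq, path) {
  check_lfq(lfq)
  vals <- lfq
  if (identical(lfq_scale(lfq), "log2")) {
    vals$intensity <- 2^vals$intensity
  }
  wide <- vals |>
    mutate(intensity = ifelse(is.na(.data$intensity), 0, .data$intensity)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "intensity",
                       names_prefix = "LFQ intensity ")
  out <- proteins |>
    transmute(
      `Protein IDs` = .data$protein_id,
      `Gene names` = .data$gene_name,
      `Unique peptides` = .data$n_unique_peptides,
      Reverse = ifelse(.data$reverse, "+", ""),
      `Potential contaminant` = ifelse(.data$contaminant, "+", "")
    ) |>
    left_join(wide, by = c("Protein IDs" = "protein_id"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a proteinGroups-dialect table
#'
#' Parses the quantification software's protein-group output: protein
#' metadata plus one `LFQ intensity <sample>` column per sample. Zero LFQ
#' values mean "not quantified" and are turned into explicit missing values.
#' Semicolon-separated protein-group ids are collapsed to their leading
#' (razor) id; the full list is kept as metadata.
#'
#' @param path Path to a tab-separated proteinGroups file with a header row.
#' @return A list with `proteins` (tibble: `protein_id`, `protein_ids`,
#'   `gene_name`, `n_unique_peptides`, `reverse`, `contaminant`) and `lfq`
#'   (long raw-scale LFQ tibble, `NA` marking missing cells).
#' @export
read_protein_groups <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  lfq_cols <- grep("^LFQ intensity ", names(raw), value = TRUE)
  if (length(lfq_cols) == 0) {
    abort("Not a proteinGroups table: no 'LFQ intensity <sample>' columns found.")
  }
  id_col <- if ("Protein IDs" %in% names(raw)) "Protein IDs" else {
    abort("Not a proteinGroups table: no 'Protein IDs' column.")
  }
  ids_full <- as.character(raw[[id_col]])
  ids <- vapply(strsplit(ids_full, ";", fixed = TRUE), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicated protein ids: %s",
                  paste(head(dups, 5), collapse = ", ")))
  }
  flag <- function(col) {
    if (col %in% names(raw)) {
      !is.na(raw[[col]]) & raw[[col]] == "+"
    } else {
      rep(FALSE, nrow(raw))
    }
  }
  n_pep <- if ("Unique peptides" %in% names(raw)) {
    as.integer(raw[["Unique peptides"]])
  } else {
    rep(NA_integer_, nrow(raw))
  }
  proteins <- tibble(
    protein_id = ids,
    protein_ids = ids_full,
    gene_name = if ("Gene names" %in% names(raw)) {
      as.character(raw[["Gene names"]])
    } else {
      NA_character_
    },
    n_unique_peptides = n_pep,
    reverse = flag("Reverse"),
    contaminant = flag("Potential contaminant")
  )
  mat <- as.matrix(raw[, lfq_cols, drop = FALSE])
  mode(mat) <- "double"
  if (any(mat < 0, na.rm = TRUE)) {
    abort("Negative raw LFQ intensities found.")
  }
  mat[mat == 0] <- NA_real_
  rownames(mat) <- ids
  colnames(mat) <- sub("^LFQ intensity ", "", lfq_cols)
  list(proteins = proteins, lfq = as_lfq_tbl(mat, scale = "raw"))
}

#' Filter protein groups before modeling
#'
#' Applies the standard pre-modeling filters, conjunctively: drop reverse
#' hits and potential contaminants; drop proteins identified with fewer than
#' `min_unique_peptides` unique peptides; drop proteins not quantified in at
#' least `min_replicates` replicates of at least one (isoform, genotype)
#' condition.
#'
#' @param proteins Protein record tibble (see [read_protein_groups()]).
#' @param lfq Long LFQ tibble.
#' @param design Experiment design tibble (see [prdx_design()]).
#' @param min_unique_peptides Minimum unique peptide count (default 3).
#' @param min_replicates Minimum replicates quantified within one condition
#'   (default 2).
#' @return A list with filtered `proteins` and `lfq`, and `removed`, a tibble
#'   of per-rule removal counts (a protein failing several rules is counted
#'   under each).
#' @export
filter_proteins <- function(proteins, lfq, design,
                            min_unique_peptides = 3L,
                            min_replicates = 2L) {
  check_lfq(lfq)
  check_design(design)
  extra <- setdiff(unique(lfq$sample_id), design$sample_id)
  if (length(extra) > 0) {
    abort(sprintf("`design` does not cover samples: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  bad_decoy <- proteins$reverse | proteins$contaminant
  bad_pep <- !is.na(proteins$n_unique_peptides) &
    proteins$n_unique_peptides < min_unique_peptides

  cond_counts <- lfq |>
    inner_join(design, by = "sample_id") |>
    summarise(n_obs = sum(!is.na(.data$intensity)),
              .by = c("protein_id", "isoform", "genotype")) |>
    summarise(max_reps = max(.data$n_obs), .by = "protein_id")
  reps_ok <- setNames(cond_counts$max_reps >= min_replicates,
                      cond_counts$protein_id)
  bad_reps <- !proteins$protein_id %in% names(reps_ok)[reps_ok]

  keep <- !(bad_decoy | bad_pep | bad_reps)
  removed <- tibble(
    rule = c("reverse_or_contaminant", "unique_peptides", "replication"),
    n_removed = c(sum(bad_decoy), sum(bad_pep), sum(bad_reps))
  )
  kept_ids <- proteins$protein_id[keep]
  list(
    proteins = proteins[keep, , drop = FALSE],
    lfq = set_lfq_scale(
      lfq |> filter(.data$protein_id %in% kept_ids),
      lfq_scale(lfq)
    ),
    removed = removed
  )
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Tibble with `protein_id` (the full FASTA header word) and
#'   `sequence` (uppercased). Errors on empty files or non-residue
#'   characters.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    abort(sprintf("Empty FASTA file: %s", path))
  }
  out <- tibble(
    protein_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(toupper(as.character(seqs)))
  )
  bad <- stringr::str_detect(out$sequence,
                             paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"))
  if (any(bad)) {
    abort(sprintf("Non-standard residues in sequences: %s",
                  paste(head(out$protein_id[bad], 5), collapse = ", ")))
  }
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs Tibble with `protein_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(setNames(seqs$sequence, seqs$protein_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference identifier list
#'
#' One identifier per line (single-column TSV, optional `protein_id` /
#' `id`-style header), e.g. a redox-sensitive protein reference.
#'
#' @param path File path.
#' @return Character vector of unique ids, order of first appearance.
#' @export
read_reference_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    abort(sprintf("Empty reference list: %s", path))
  }
  if (tolower(lines[1]) %in% c("protein_id", "id", "identifier", "uniprot")) {
    lines <- lines[-1]
  }
  unique(lines)
}
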