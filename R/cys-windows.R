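# Cysteine-centered sequence windows, shuffled backgrounds, amino-acid
# composition enrichment, and iterative motif discovery.

#' Extract cysteine-centered windows
#'
#' One window of `2 * half_width + 1` residues per cysteine, centered on it;
#' positions beyond the termini are padded with `-`. Pads are excluded from
#' all downstream counting.
#'
#' @param seqs Tibble with `protein_id` and `sequence` (uppercase), or a
#'   named character vector.
#' @param half_width Flank width (default 4, i.e. 9-mer windows).
#' @return Tibble with `protein_id`, `position` (1-based cysteine position)
#'   and `window`.
#' @export
extract_cys_windows <- function(seqs, half_width = 4L) {
  if (!is.data.frame(seqs)) {
    seqs <- tibble(protein_id = names(seqs), sequence = unname(seqs))
  }
  w <- 2L * half_width + 1L
  purrr::map2_dfr(seqs$protein_id, seqs$sequence, function(id, s) {
    chars <- strsplit(s, "")[[1]]
    cys <- which(chars == "C")
    if (length(cys) == 0) {
      return(NULL)
    }
    padded <- c(rep("-", half_width), chars, rep("-", half_width))
    tibble(
      protein_id = id,
      position = cys,
      window = vapply(cys, function(p) {
        paste(padded[p:(p + w - 1L)], collapse = "")
      }, character(1))
    )
  })
}

#' Shuffled-sequence background windows
#'
#' Independently permutes each sequence's residues (composition preserved
#' exactly) `n_shuffles` times and re-extracts cysteine-centered windows
#' from the shuffled sequences, giving a background with the same per-protein
#' composition and cysteine counts but no positional structure.
#'
#' @inheritParams extract_cys_windows
#' @param n_shuffles Number of shuffles per sequence (>= 1).
#' @param seed Integer seed.
#' @return Window tibble (as [extract_cys_windows()]) with a `shuffle`
#'   index column.
#' @export
shuffle_background <- function(seqs, n_shuffles = 100L, half_width = 4L,
                               seed = 1L) {
  if (n_shuffles < 1) {
    abort("`n_shuffles` must be at least 1.")
  }
  if (!is.data.frame(seqs)) {
    seqs <- tibble(protein_id = names(seqs), sequence = unname(seqs))
  }
  local_seed(seed, SEED_OFFSET[["shuffle"]], {
    purrr::map_dfr(seq_len(n_shuffles), function(b) {
      shuffled <- seqs |>
        mutate(sequence = vapply(.data$sequence, function(s) {
          paste(sample(strsplit(s, "")[[1]]), collapse = "")
        }, character(1), USE.NAMES = FALSE))
      extract_cys_windows(shuffled, half_width = half_width) |>
        mutate(shuffle = b)
    })
  })
}

# flanking residue counts (center and pads excluded) for a window set
flank_counts <- function(windows) {
  if (nrow(windows) == 0) {
    return(setNames(rep(0L, length(AA_ALPHABET)), AA_ALPHABET))
  }
  w <- nchar(windows$window[1])
  center <- (w + 1L) / 2L
  chars <- strsplit(windows$window, "")
  flat <- unlist(lapply(chars, function(x) x[-center]))
  flat <- flat[flat != "-"]
  tab <- table(factor(flat, levels = AA_ALPHABET))
  setNames(as.integer(tab), AA_ALPHABET)
}

#' Amino-acid composition enrichment around cysteines
#'
#' Compares the flanking residue composition (window center and pad
#' positions excluded) of a foreground window set against a control set.
#' Fold change per residue uses a 0.5 pseudocount on both counts; the
#' p-value is a two-sided binomial test of the foreground count against the
#' control frequency, BH-adjusted over the 20 residues.
#'
#' @param fg_windows,ctrl_windows Window tibbles from
#'   [extract_cys_windows()] / [shuffle_background()]; both non-empty.
#' @param pseudocount Added to both counts for the fold change.
#' @return Tibble with one row per residue: `residue`, `n_fg`, `n_ctrl`,
#'   `freq_fg`, `freq_ctrl`, `fold`, `p`, `q`.
#' @export
aa_composition_enrichment <- function(fg_windows, ctrl_windows,
                                      pseudocount = 0.5) {
  if (nrow(fg_windows) == 0 || nrow(ctrl_windows) == 0) {
    abort("Foreground and control window sets must be non-empty.")
  }
  fg <- flank_counts(fg_windows)
  ctrl <- flank_counts(ctrl_windows)
  n_fg <- sum(fg)
  n_ctrl <- sum(ctrl)
  freq_fg <- (fg + pseudocount) / (n_fg + 20 * pseudocount)
  freq_ctrl <- (ctrl + pseudocount) / (n_ctrl + 20 * pseudocount)
  p0 <- ctrl / n_ctrl
  p <- vapply(AA_ALPHABET, function(aa) {
    binom.test(fg[[aa]], n_fg, p = p0[[aa]],
               alternative = "two.sided")$p.value
  }, double(1))
  tibble(
    residue = AA_ALPHABET,
    n_fg = unname(fg),
    n_ctrl = unname(ctrl),
    freq_fg = unname(freq_fg),
    freq_ctrl = unname(freq_ctrl),
    fold = unname(freq_fg / freq_ctrl),
    p = unname(p),
    q = p.adjust(unname(p), method = "BH")
  )
}

# does each window match residue `res` at window position `pos`?
window_matches <- function(windows, pos, res) {
  substr(windows, pos, pos) == res
}

#' Iterative motif discovery in fixed-width cysteine windows
#'
#' A motif-x-style greedy search. Repeatedly finds the (position, residue)
#' pair with the smallest one-sided binomial p-value for enrichment of the
#' foreground windows over the control frequency; if `p < p_fix` and at
#' least `min_support` foreground windows carry it, the pair is fixed and
#' both window sets are filtered to the matching windows. When no further
#' pair qualifies, the accumulated pattern (if any position was fixed) is
#' emitted as a motif, its foreground windows are removed, the control is
#' reset, and the search restarts. Ties break deterministically by
#' (p-value, position, residue).
#'
#' @param fg_windows,ctrl_windows Window tibbles (all windows the same
#'   length, center residue `C`).
#' @param min_support Minimum foreground windows matching the motif.
#' @param p_fix Binomial p-value threshold for fixing a position.
#' @return Tibble with `motif` (pattern string, `.` wildcards), `support`,
#'   `fg_size`, `fold` (foreground vs control match-rate ratio), `score`
#'   (sum of `-log10 p` over fixed steps), and `n_fixed`.
#' @export
motif_x <- function(fg_windows, ctrl_windows, min_support = 10L,
                    p_fix = 1e-4) {
  fg <- fg_windows$window
  ctrl0 <- ctrl_windows$window
  widths <- unique(nchar(c(fg, ctrl0)))
  if (length(widths) != 1) {
    abort("All windows must have the same length.")
  }
  w <- widths
  center <- (w + 1L) / 2L
  positions <- setdiff(seq_len(w), center)

  motifs <- list()
  repeat {
    if (length(fg) < min_support) break
    cur_fg <- fg
    cur_ctrl <- ctrl0
    fixed <- character(0)
    fixed_pos <- integer(0)
    score <- 0
    repeat {
      n_fg <- length(cur_fg)
      n_ctrl <- length(cur_ctrl)
      # stop growing when either set is too small to assess enrichment
      if (n_fg < min_support || n_ctrl < min_support) break
      best <- NULL
      for (pos in setdiff(positions, fixed_pos)) {
        fg_chars <- substr(cur_fg, pos, pos)
        ctrl_chars <- substr(cur_ctrl, pos, pos)
        fg_tab <- table(factor(fg_chars, levels = AA_ALPHABET))
        ctrl_tab <- table(factor(ctrl_chars, levels = AA_ALPHABET))
        for (res in AA_ALPHABET) {
          k <- fg_tab[[res]]
          if (k < min_support) next
          # 0.5 pseudocount: a residue absent from the filtered control must
          # not yield p = 0 and trigger runaway position fixing
          p_bg <- max(ctrl_tab[[res]], 0.5) / n_ctrl
          pval <- stats::pbinom(k - 1, n_fg, p_bg, lower.tail = FALSE)
          if (is.null(best) ||
              pval < best$p - 1e-15 ||
              (abs(pval - best$p) <= 1e-15 &&
                 (pos < best$pos || (pos == best$pos && res < best$res)))) {
            best <- list(p = pval, pos = pos, res = res, k = k)
          }
        }
      }
      if (is.null(best) || best$p >= p_fix) break
      fixed_pos <- c(fixed_pos, best$pos)
      fixed <- c(fixed, best$res)
      score <- score - log10(max(best$p, 1e-300))
      cur_fg <- cur_fg[window_matches(cur_fg, best$pos, best$res)]
      cur_ctrl <- cur_ctrl[window_matches(cur_ctrl, best$pos, best$res)]
    }
    if (length(fixed_pos) == 0) break
    pattern <- rep(".", w)
    pattern[center] <- "C"
    pattern[fixed_pos] <- fixed
    pattern <- paste(pattern, collapse = "")
    fg_rate <- length(cur_fg) / length(fg)
    ctrl_rate <- length(cur_ctrl) / length(ctrl0)
    motifs[[length(motifs) + 1]] <- tibble(
      motif = pattern,
      support = length(cur_fg),
      fg_size = length(fg),
      fold = if (ctrl_rate > 0) fg_rate / ctrl_rate else Inf,
      score = score,
      n_fixed = length(fixed_pos)
    )
    match_motif <- rep(TRUE, length(fg))
    for (k in seq_along(fixed_pos)) {
      match_motif <- match_motif & window_matches(fg, fixed_pos[k], fixed[k])
    }
    fg <- fg[!match_motif]
  }
  if (length(motifs) == 0) {
    return(tibble(motif = character(), support = integer(),
                  fg_size = integer(), fold = double(), score = double(),
                  n_fixed = integer()))
  }
  bind_rows(motifs)
}
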