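# Global protein alignment with affine gaps and free end gaps, plus the
# pairwise similarity matrix used to compare bait isoform sequences.

get_substitution_matrix <- function(substitution_matrix) {
  if (is.matrix(substitution_matrix)) {
    return(substitution_matrix)
  }
  e <- new.env()
  utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
  get(substitution_matrix, envir = e)
}

check_residues <- function(s, arg) {
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue '%s' at position %d of `%s`.",
                  chars[bad[1]], bad[1], arg))
  }
  chars
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Optimal global alignment of two protein sequences under an affine gap
#' model (a gap of length L costs `gap_open + L * gap_extend`) with end gaps
#' free by default, the convention of the classic pairwise alignment tools
#' used for full-length protein comparisons. Traceback ties are broken
#' deterministically: diagonal, then gap in the second sequence, then gap in
#' the first.
#'
#' Identity is the percentage of alignment columns with identical residues;
#' similarity the percentage of columns whose substitution score is
#' positive. Both use the full alignment length (gap columns included).
#'
#' @param seq_a,seq_b Non-empty residue strings (20 standard amino acids).
#' @param substitution_matrix Scoring matrix name (a Biostrings data set,
#'   default `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Gap opening and extension penalties (positive).
#' @param penalize_end_gaps Charge terminal gaps too (default `FALSE`).
#' @return Object of class `prx_alignment`: `aligned_a`, `aligned_b`,
#'   `score`, `length`, `identity`, `similarity`.
#' @examples
#' al <- needleman_wunsch_align("HEAGAWGHEE", "PAWHEAE")
#' al$similarity
#' @export
needleman_wunsch_align <- function(seq_a, seq_b,
                                   substitution_matrix = "BLOSUM62",
                                   gap_open = 10, gap_extend = 0.5,
                                   penalize_end_gaps = FALSE) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    abort("Sequences must be non-empty.")
  }
  a <- check_residues(toupper(seq_a), "seq_a")
  b <- check_residues(toupper(seq_b), "seq_b")
  sub <- get_substitution_matrix(substitution_matrix)
  n <- length(a); m <- length(b)
  NEG <- -1e18

  # Gotoh: M = a[i] aligned to b[j]; X = gap in b (a[i] unmatched);
  # Y = gap in a (b[j] unmatched). Scores stored per row.
  open_cost <- gap_open + gap_extend
  end_open <- if (penalize_end_gaps) open_cost else 0
  end_ext <- if (penalize_end_gaps) gap_extend else 0

  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Yg <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) {
    X[2:(n + 1), 1] <- -(end_open + end_ext * (seq_len(n) - 1))
  }
  if (m >= 1) {
    Yg[1, 2:(m + 1)] <- -(end_open + end_ext * (seq_len(m) - 1))
  }

  for (i in seq_len(n)) {
    si <- sub[a[i], b]
    for (j in seq_len(m)) {
      best_prev <- max(M[i, j], X[i, j], Yg[i, j])
      M[i + 1, j + 1] <- best_prev + si[j]
      # gap in b: consume a[i]; free if trailing (j == m) and ends-free
      xo <- if (!penalize_end_gaps && j == m) 0 else open_cost
      xe <- if (!penalize_end_gaps && j == m) 0 else gap_extend
      X[i + 1, j + 1] <- max(M[i, j + 1] - xo, X[i, j + 1] - xe,
                             Yg[i, j + 1] - xo)
      yo <- if (!penalize_end_gaps && i == n) 0 else open_cost
      ye <- if (!penalize_end_gaps && i == n) 0 else gap_extend
      Yg[i + 1, j + 1] <- max(M[i + 1, j] - yo, Yg[i + 1, j] - ye,
                              X[i + 1, j] - yo)
    }
  }
  fin <- c(M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Yg[n + 1, m + 1])
  score <- max(fin)
  state <- names(fin)[which.max(fin)]  # ties: M, then X, then Y

  # traceback
  al_a <- character(0); al_b <- character(0)
  i <- n; j <- m
  tol <- 1e-9
  while (i > 0 || j > 0) {
    if (state == "M") {
      s <- sub[a[i], b[j]]
      al_a <- c(a[i], al_a); al_b <- c(b[j], al_b)
      prev <- c(M = M[i, j], X = X[i, j], Y = Yg[i, j])
      target <- M[i + 1, j + 1] - s
      state <- names(prev)[which(abs(prev - target) < tol)][1]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      al_a <- c(a[i], al_a); al_b <- c("-", al_b)
      xo <- if (!penalize_end_gaps && j == m) 0 else open_cost
      xe <- if (!penalize_end_gaps && j == m) 0 else gap_extend
      cand <- c(M = M[i, j + 1] - xo, X = X[i, j + 1] - xe,
                Y = Yg[i, j + 1] - xo)
      state <- names(cand)[which(abs(cand - X[i + 1, j + 1]) < tol)][1]
      i <- i - 1
    } else {
      al_a <- c("-", al_a); al_b <- c(b[j], al_b)
      yo <- if (!penalize_end_gaps && i == n) 0 else open_cost
      ye <- if (!penalize_end_gaps && i == n) 0 else gap_extend
      cand <- c(M = M[i + 1, j] - yo, Y = Yg[i + 1, j] - ye,
                X = X[i + 1, j] - yo)
      state <- names(cand)[which(abs(cand - Yg[i + 1, j + 1]) < tol)][1]
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- "Y"
    if (j == 0 && i > 0) state <- "X"
  }

  len <- length(al_a)
  ident <- sum(al_a == al_b & al_a != "-")
  pos <- sum(vapply(seq_len(len), function(k) {
    al_a[k] != "-" && al_b[k] != "-" && sub[al_a[k], al_b[k]] > 0
  }, logical(1)))
  structure(
    list(
      aligned_a = paste(al_a, collapse = ""),
      aligned_b = paste(al_b, collapse = ""),
      score = unname(score),
      length = len,
      identity = 100 * ident / len,
      similarity = 100 * pos / len
    ),
    class = "prx_alignment"
  )
}

#' @export
print.prx_alignment <- function(x, ...) {
  cat(sprintf(
    "<prx_alignment> score %.1f, length %d, identity %.1f%%, similarity %.1f%%\n",
    x$score, x$length, x$identity, x$similarity
  ))
  w <- 60
  for (k in seq(1, nchar(x$aligned_a), by = w)) {
    cat(substr(x$aligned_a, k, k + w - 1), "\n")
    cat(substr(x$aligned_b, k, k + w - 1), "\n\n")
  }
  invisible(x)
}

#' Pairwise similarity matrix between protein sequences
#'
#' Aligns every pair globally and tabulates the similarity percentage
#' (positive-substitution columns over alignment length).
#'
#' @param seqs Named character vector of sequences, or a tibble with
#'   `protein_id` and `sequence`.
#' @param ... Passed to [needleman_wunsch_align()].
#' @return Symmetric numeric matrix with a 100 diagonal.
#' @export
pairwise_similarity_matrix <- function(seqs, ...) {
  if (is.data.frame(seqs)) {
    seqs <- setNames(seqs$sequence, seqs$protein_id)
  }
  if (length(seqs) < 2) {
    abort("Need at least two sequences.")
  }
  k <- length(seqs)
  out <- matrix(100, k, k, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      al <- needleman_wunsch_align(seqs[[i]], seqs[[j]], ...)
      out[i, j] <- al$similarity
      out[j, i] <- al$similarity
    }
  }
  out
}
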