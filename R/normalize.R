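# log2 transform and missing-value-aware quantile normalization.

#' Log2-transform a raw-scale LFQ table
#'
#' @param lfq Long raw-scale LFQ tibble; all non-missing values must be
#'   positive.
#' @return The table with each observed cell replaced by its base-2
#'   logarithm; the missing pattern is untouched and the scale tag flips to
#'   `"log2"`.
#' @export
log2_transform <- function(lfq) {
  check_lfq(lfq)
  if (identical(lfq_scale(lfq), "log2")) {
    abort("`lfq` is already on the log2 scale.")
  }
  bad <- !is.na(lfq$intensity) & lfq$intensity <= 0
  if (any(bad)) {
    where <- lfq[bad, c("protein_id", "sample_id")]
    abort(sprintf(
      "Non-positive intensities cannot be log-transformed (first offender: protein %s, sample %s).",
      where$protein_id[1], where$sample_id[1]
    ))
  }
  out <- lfq
  out$intensity <- log2(out$intensity)
  set_lfq_scale(out, "log2")
}

#' Quantile-normalize a log2 LFQ table across samples
#'
#' Forces every sample's intensity distribution onto a common reference of
#' per-rank means, correcting jointly for protein loading and IP efficiency.
#' Missing values stay missing; observed values are mapped through their
#' within-sample rank onto the reference distribution interpolated on a
#' common quantile grid (so samples with different numbers of observed
#' values are handled without imputation). For complete data this reduces to
#' classical quantile normalization: all column-sorted vectors become the
#' across-sample mean of order statistics.
#'
#' @param lfq Long log2-scale LFQ tibble with at least 2 samples, each with
#'   at least 2 observed values.
#' @return Normalized long log2-scale tibble; within-sample rank order is
#'   preserved.
#' @export
quantile_normalize <- function(lfq) {
  check_lfq(lfq)
  mat <- as_intensity_matrix(lfq)
  if (ncol(mat) < 2) {
    abort("Quantile normalization needs at least 2 samples.")
  }
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2)) {
    abort(sprintf("Samples with fewer than 2 observed values: %s",
                  paste(colnames(mat)[n_obs < 2], collapse = ", ")))
  }
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(norm) <- dimnames(mat)
  set_lfq_scale(as_lfq_tbl(norm, scale = "log2"), lfq_scale(lfq) %||% "log2")
}
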