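# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed + offset`.
# The caller's .Random.seed is restored afterwards, so generator functions are
# reproducible without clobbering the session RNG. Offsets give each generator
# op its own stream derived from one config seed.
local_seed <- function(seed, offset = 0L, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  # large-prime spacing keeps per-op streams from colliding across nearby
  # user seeds (seed s, op k+1 must not equal seed s+1, op k)
  set.seed((as.integer(seed) + as.integer(offset) * 1000003L) %% 2147483647L)
  force(expr)
}

# seed offsets: one stream per generator op
SEED_OFFSET <- c(
  truth = 0L, lfq = 1L, sequences = 2L, compartments = 3L,
  calibration = 4L, shuffle = 5L
)

#' Intensity scale of an LFQ table
#'
#' Long LFQ tables carry a `"scale"` attribute (`"raw"` or `"log2"`) so that
#' transformations can check they are applied in the right order.
#'
#' @param lfq A long LFQ tibble.
#' @return `"raw"` or `"log2"` (or `NA` if untagged).
#' @export
lfq_scale <- function(lfq) {
  attr(lfq, "scale") %||% NA_character_
}

set_lfq_scale <- function(lfq, scale) {
  attr(lfq, "scale") <- scale
  lfq
}

check_lfq <- function(lfq, arg = "lfq") {
  need <- c("protein_id", "sample_id", "intensity")
  miss <- setdiff(need, names(lfq))
  if (length(miss) > 0) {
    abort(sprintf(
      "`%s` must be a long LFQ table with columns %s (missing: %s).",
      arg, paste(need, collapse = ", "), paste(miss, collapse = ", ")
    ))
  }
  invisible(lfq)
}

check_design <- function(design, arg = "design") {
  need <- c("sample_id", "isoform", "genotype", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    abort(sprintf(
      "`%s` must have columns %s (missing: %s).",
      arg, paste(need, collapse = ", "), paste(miss, collapse = ", ")
    ))
  }
  if (anyDuplicated(design$sample_id)) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  invisible(design)
}

#' Convert a long LFQ table to a proteins-by-samples matrix
#'
#' @param lfq Long LFQ tibble with `protein_id`, `sample_id`, `intensity`.
#' @param samples Optional sample ordering (defaults to first appearance).
#' @return Numeric matrix, proteins in rows, samples in columns; `NA` marks
#'   missing (not-quantified) cells.
#' @export
as_intensity_matrix <- function(lfq, samples = NULL) {
  check_lfq(lfq)
  samples <- samples %||% unique(lfq$sample_id)
  proteins <- unique(lfq$protein_id)
  mat <- matrix(NA_real_, nrow = length(proteins), ncol = length(samples),
                dimnames = list(proteins, samples))
  idx <- cbind(match(lfq$protein_id, proteins), match(lfq$sample_id, samples))
  keep <- !is.na(idx[, 2])
  mat[idx[keep, , drop = FALSE]] <- lfq$intensity[keep]
  mat
}

#' Convert a proteins-by-samples matrix to a long LFQ table
#'
#' @param mat Numeric matrix with protein row names and sample column names.
#' @param scale Intensity scale tag, `"raw"` or `"log2"`.
#' @return Long LFQ tibble (`NA` cells kept, marking missingness explicitly).
#' @export
as_lfq_tbl <- function(mat, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  out <- tibble(
    protein_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    intensity = as.vector(mat)
  )
  set_lfq_scale(out, scale)
}
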