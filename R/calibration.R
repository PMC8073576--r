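# Label-randomization calibration of the log2 fold-change threshold.

#' Calibrate the fold-change threshold by label randomization
#'
#' Repeats the WT-vs-catalytic-dead comparison `n_perm` times with the two
#' genotype labels shuffled within each isoform (replicate structure and
#' per-sample dropout curves preserved), pools the randomized absolute log2
#' fold changes, and sets the threshold `tau` at their `1 - alpha` quantile:
#' the fold change at which a fraction `alpha` of the randomized data is
#' still included. Also records which fraction of the real (unpermuted)
#' fold changes exceed `tau`.
#'
#' @param lfq Long log2-scale LFQ tibble (filtered, normalized).
#' @param design Experiment design with both genotypes in each isoform.
#' @param genotypes Length-2 genotype pair to randomize between.
#' @param n_perm Number of label permutations (>= 1).
#' @param alpha Included fraction of randomized data defining the threshold.
#' @param curves Optional dropout curves (estimated once on the real design
#'   and reused across permutations; the detection limit is a property of
#'   the sample, not of its label).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `prx_calibration`: `tau`, `alpha`, `n_perm`,
#'   `perm_deltas` (pooled randomized `|delta|`), `real_deltas`,
#'   `included_fraction_real`, and the real contrast table.
#' @export
randomize_labels_fdr <- function(lfq, design,
                                 genotypes = c("WT", "CPRS"),
                                 n_perm = 100L,
                                 alpha = 0.05,
                                 curves = NULL,
                                 seed = 1L) {
  check_lfq(lfq)
  check_design(design)
  if (n_perm < 1) {
    abort("`n_perm` must be at least 1.")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  sub <- design |> filter(.data$genotype %in% genotypes)
  counts <- sub |> count(.data$isoform, .data$genotype)
  if (any(counts$n < 2) || length(unique(counts$genotype)) < 2) {
    abort("Each isoform needs at least 2 samples of both genotypes to permute.")
  }
  curves <- curves %||% estimate_dropout_curves(lfq, design)

  real <- genotype_contrasts(lfq, design, genotypes = genotypes,
                             curves = curves)
  real_deltas <- abs(real$delta)

  perm_deltas <- local_seed(seed, SEED_OFFSET[["calibration"]], {
    purrr::map(seq_len(n_perm), function(b) {
      perm_design <- design |>
        mutate(genotype = {
          g <- .data$genotype
          in_pair <- g %in% genotypes
          g[in_pair] <- sample(g[in_pair])
          g
        }, .by = "isoform") |>
        mutate(condition = paste(.data$isoform, .data$genotype, sep = "_"))
      res <- genotype_contrasts(lfq, perm_design, genotypes = genotypes,
                                curves = curves)
      abs(res$delta)
    })
  })
  pooled <- unlist(perm_deltas)
  tau <- unname(quantile(pooled, probs = 1 - alpha, type = 7))

  structure(
    list(
      tau = tau,
      alpha = alpha,
      n_perm = as.integer(n_perm),
      seed = as.integer(seed),
      perm_deltas = pooled,
      perm_counts = lengths(perm_deltas),
      real_deltas = real_deltas,
      real_contrasts = real,
      included_fraction_real = mean(real_deltas > tau),
      genotypes = genotypes
    ),
    class = "prx_calibration"
  )
}

#' @export
print.prx_calibration <- function(x, ...) {
  cat(sprintf(
    "<prx_calibration> tau = %.3f (alpha = %.2f, %d permutations)\n  real |delta| > tau: %.1f%%\n",
    x$tau, x$alpha, x$n_perm, 100 * x$included_fraction_real
  ))
  invisible(x)
}

#' Estimate the FDR at a fold-change threshold
#'
#' The expected number of randomized fold changes above the threshold per
#' permutation, divided by the number of real fold changes above it
#' (clipped to `[0, 1]`). With no real discoveries the FDR is undefined and
#' reported as `NA`.
#'
#' @param calibration A `prx_calibration`, or `NULL` if `real_deltas` /
#'   `perm_deltas` / `n_perm` are given directly.
#' @param tau Threshold on `|delta|` (>= 0).
#' @param real_deltas,perm_deltas,n_perm Raw inputs, used when
#'   `calibration` is `NULL`.
#' @return Tibble with `tau`, `fdr`, `n_real_included`,
#'   `frac_real_included`, `mean_perm_included`.
#' @export
fdr_at_threshold <- function(calibration = NULL, tau,
                             real_deltas = NULL, perm_deltas = NULL,
                             n_perm = NULL) {
  if (!is.null(calibration)) {
    real_deltas <- abs(calibration$real_deltas)
    perm_deltas <- abs(calibration$perm_deltas)
    n_perm <- calibration$n_perm
  }
  if (any(tau < 0)) {
    abort("`tau` must be non-negative.")
  }
  purrr::map_dfr(tau, function(t1) {
    n_real <- sum(real_deltas > t1)
    mean_perm <- sum(perm_deltas > t1) / n_perm
    fdr <- if (n_real == 0) NA_real_ else min(mean_perm / n_real, 1)
    tibble(
      tau = t1,
      fdr = fdr,
      n_real_included = n_real,
      frac_real_included = n_real / length(real_deltas),
      mean_perm_included = mean_perm
    )
  })
}
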