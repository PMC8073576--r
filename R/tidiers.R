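# broom-style tidy()/glance() methods for fitted objects.

#' Tidy a dropout-model fit
#'
#' @param x A `prx_fit`.
#' @param ... Unused.
#' @return Long tibble: one row per (protein, condition) with the fitted
#'   log2 mean, residual sd, observation count and convergence flag.
#' @export
tidy.prx_fit <- function(x, ...) {
  conds <- x$conditions
  tibble(
    protein_id = rep(rownames(x$mu), times = length(conds)),
    condition = rep(conds, each = nrow(x$mu)),
    mu = as.vector(x$mu),
    n_obs = as.vector(x$n_obs),
    sigma = rep(unname(x$sigma), times = length(conds)),
    converged = rep(unname(x$converged), times = length(conds))
  )
}

#' Summarize a dropout-model fit
#'
#' @param x A `prx_fit`.
#' @param ... Unused.
#' @return One-row tibble: protein/sample/condition counts, convergence
#'   rate, median residual sd, total log-likelihood.
#' @export
glance.prx_fit <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$mu),
    n_samples = ncol(x$Y),
    n_conditions = length(x$conditions),
    prop_converged = mean(x$converged),
    sigma_median = median(x$sigma),
    log_lik = sum(x$objective)
  )
}

#' Tidy a calibration result
#'
#' @param x A `prx_calibration`.
#' @param ... Unused.
#' @return One row per permutation with its count and mean |delta|.
#' @export
tidy.prx_calibration <- function(x, ...) {
  idx <- rep(seq_len(x$n_perm), x$perm_counts)
  tibble(
    permutation = seq_len(x$n_perm),
    n_deltas = x$perm_counts,
    mean_abs_delta = vapply(split(x$perm_deltas, idx), mean, double(1),
                            USE.NAMES = FALSE)
  )
}

#' Summarize a calibration result
#'
#' @param x A `prx_calibration`.
#' @param ... Unused.
#' @return One-row tibble with `tau`, `alpha`, `n_perm`, the real included
#'   fraction and the estimated FDR at `tau`.
#' @export
glance.prx_calibration <- function(x, ...) {
  fdr <- fdr_at_threshold(x, tau = x$tau)
  tibble(
    tau = x$tau,
    alpha = x$alpha,
    n_perm = x$n_perm,
    included_fraction_real = x$included_fraction_real,
    fdr_at_tau = fdr$fdr
  )
}

#' Tidy an alignment
#'
#' @param x A `prx_alignment`.
#' @param ... Unused.
#' @return One-row tibble with score, length, identity and similarity.
#' @export
tidy.prx_alignment <- function(x, ...) {
  tibble(
    score = x$score, length = x$length,
    identity = x$identity, similarity = x$similarity
  )
}

#' Tidy a mechanism split
#'
#' @param x A `prx_mechanism`.
#' @param ... Unused.
#' @return The per-protein mechanism assignment tibble.
#' @export
tidy.prx_mechanism <- function(x, ...) {
  x$assignments
}

#' Summarize a mechanism split
#'
#' @param x A `prx_mechanism`.
#' @param ... Unused.
#' @return One-row tibble with group sizes and the relay percentage.
#' @export
glance.prx_mechanism <- function(x, ...) {
  tibble(
    n_soh = x$n_soh, n_ss = x$n_ss, ss_pct = x$ss_pct,
    n_crs_only = length(x$crs_only)
  )
}
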