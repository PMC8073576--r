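# shared design/curves for direct fits
two_cond_design <- function(n_rep = 3) {
  tibble::tibble(
    sample_id = paste0("S", seq_len(2 * n_rep)),
    isoform = "PRDX1",
    genotype = rep(c("WT", "CPRS"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    condition = rep(c("A", "B"), each = n_rep)
  )
}

flat_curves <- function(design, rho, zeta = 1) {
  tibble::tibble(sample_id = design$sample_id, rho = rho, zeta = zeta,
                 n_proxy = 100L, fallback = FALSE)
}

test_that("the closed-form missing probability matches quadrature", {
  set.seed(31)
  worst <- 0
  for (k in 1:40) {
    mu <- runif(1, 15, 30)
    sigma <- runif(1, 0.1, 3)
    rho <- runif(1, 18, 24)
    zeta <- runif(1, 0.3, 2)
    cf <- exp(missing_loglik(mu, sigma, rho, zeta))
    worst <- max(worst, abs(cf - quad_missing_prob(mu, sigma, rho, zeta)))
  }
  expect_lt(worst, 1e-6)
  # exact symmetry at the midpoint, for any widths
  expect_equal(exp(missing_loglik(20, 0.7, 20, 1.3)), 0.5)
  # deep tail
  expect_lt(exp(missing_loglik(30, 1, 20, 1)), 1e-10)
  expect_error(missing_loglik(20, -1, 20, 1), "positive")
})

test_that("dropout curves fall back on complete data and reject empty samples", {
  design <- two_cond_design()
  m <- matrix(rnorm(60, 25, 1), 10, 6,
              dimnames = list(paste0("p", 1:10), design$sample_id))
  cv <- estimate_dropout_curves(as_lfq_tbl(m, "log2"), design)
  expect_true(all(cv$fallback))
  expect_equal(cv$zeta, rep(1, 6))
  expect_equal(cv$rho,
               apply(m, 2, quantile, probs = 0.1, names = FALSE)[cv$sample_id],
               ignore_attr = TRUE)
  m2 <- m
  m2[, "S3"] <- NA
  expect_error(estimate_dropout_curves(as_lfq_tbl(m2, "log2"), design), "S3")
})

test_that("dropout curves recover the generating curve up to the proxy-set tilt", {
  # The proxy estimator averages observed values of partially missing
  # proteins; only values above the limit are observed, so rho inherits a
  # small upward selection tilt (documented); zeta is near-unbiased.
  truth <- generate_interactome_truth(n_background = 2000, n_interactors = 0,
                                      n_decoys = 0, baseline_mean = 21,
                                      baseline_sd = 3,
                                      low_peptide_fraction = 0, seed = 33)
  design <- prdx_design(isoforms = "PRDX1")
  sim <- simulate_lfq_experiment(truth, design,
                                 dropout = dropout_spec(rho = 20, zeta = 1),
                                 seed = 33)
  cv <- estimate_dropout_curves(sim$lfq, design)
  expect_true(all(!cv$fallback))
  expect_true(all(cv$rho > 20 - 0.3 & cv$rho < 20 + 0.75))
  expect_true(all(abs(cv$zeta - 1) < 0.3))
})

test_that("the fit reduces to arithmetic means without dropout and is equivariant", {
  design <- two_cond_design()
  set.seed(34)
  m <- matrix(rnorm(50 * 6, 25, 0.6), 50, 6,
              dimnames = list(paste0("p", 1:50), design$sample_id))
  cv <- flat_curves(design, rho = -50)
  fit <- fit_dropout_model(as_lfq_tbl(m, "log2"), design, curves = cv)
  expect_lt(max(abs(fit$mu[, "A"] - rowMeans(m[, 1:3]))), 1e-3)
  expect_lt(max(abs(fit$mu[, "B"] - rowMeans(m[, 4:6]))), 1e-3)
  expect_true(all(fit$converged))

  shifted <- m
  shifted[, 4:6] <- shifted[, 4:6] + 2.5
  fit2 <- fit_dropout_model(as_lfq_tbl(shifted, "log2"), design, curves = cv)
  expect_lt(max(abs((fit2$mu[, "B"] - fit$mu[, "B"]) - 2.5)), 1e-6)
  expect_lt(max(abs(fit2$mu[, "A"] - fit$mu[, "A"])), 1e-6)
})

test_that("the optimizer dominates a dense grid of its own objective", {
  set.seed(35)
  design <- tibble::tibble(
    sample_id = paste0("S", 1:6), isoform = "PRDX1", genotype = "WT",
    replicate = 1:6, condition = "A"
  )
  n <- 25
  mu_true <- runif(n, 18, 28)
  Y <- matrix(rnorm(n * 6, mu_true, 0.8), n, 6,
              dimnames = list(sprintf("p%02d", 1:n), design$sample_id))
  Y[matrix(runif(n * 6), n, 6) < pnorm((21 - Y) / 1)] <- NA
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  cv <- flat_curves(design, rho = 21)
  fit <- fit_dropout_model(as_lfq_tbl(Y, "log2"), design, curves = cv)

  sigs <- exp(seq(log(0.05), log(10), length.out = 50))
  gap <- Inf
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    obs <- y[!is.na(y)]
    n_miss <- sum(is.na(y))
    mus <- seq(min(obs) - 5, max(obs) + 5, length.out = 200)
    const <- sum(pnorm(obs - 21, log.p = TRUE))
    best <- -Inf
    for (s in sigs) {
      ll <- vapply(mus, function(mm) {
        sum(dnorm(obs, mm, s, log = TRUE)) +
          n_miss * pnorm((21 - mm) / sqrt(1 + s^2), log.p = TRUE)
      }, double(1))
      best <- max(best, max(ll) + const)
    }
    gap <- min(gap, fit$objective[i] - best)
  }
  expect_gte(gap, -1e-6)
})

test_that("an all-missing condition yields a positive, finite, bounded delta", {
  design <- two_cond_design()
  m <- matrix(NA_real_, 1, 6, dimnames = list("p1", design$sample_id))
  m[1, 1:3] <- c(27.1, 26.8, 27.3)
  cv <- flat_curves(design, rho = 22)
  fit <- fit_dropout_model(as_lfq_tbl(m, "log2"), design, curves = cv)
  expect_true(is.finite(fit$mu[1, "B"]))
  expect_lte(fit$mu[1, "B"], 22 + 1)
  res <- test_contrast(fit, c("A", "B"))
  expect_gt(res$delta, 0)
})

test_that("variance moderation matches its prior and handles degeneracies", {
  # equal variances: infinite prior df, posterior collapses to the common value
  fake <- structure(list(sigma = rep(0.5, 30),
                         n_obs = cbind(rep(3, 30), rep(3, 30))),
                    class = "prx_fit")
  md <- moderate_variances(fake)
  expect_identical(md$d0, Inf)
  expect_equal(md$sigma2_posterior, rep(0.25 * 6 / 4, 30))

  # recovery of a known scaled inverse-chi-squared prior from residual
  # variances carrying their chi-squared sampling noise (df = 4)
  set.seed(36)
  n <- 2000
  s2_true <- 4 * 0.25 / rchisq(n, 4)
  s2_obs <- s2_true * rchisq(n, 4) / 4
  fake2 <- structure(list(sigma = sqrt(s2_obs * 4 / 6),
                          n_obs = cbind(rep(3, n), rep(3, n))),
                     class = "prx_fit")
  md2 <- moderate_variances(fake2)
  expect_lt(abs(md2$d0 - 4), 1.5)
  expect_lt(abs(md2$s0_sq - 0.25) / 0.25, 0.2)

  single <- structure(list(sigma = 0.7, n_obs = cbind(3, 3)),
                      class = "prx_fit")
  expect_true(moderate_variances(single)$skipped)
})

test_that("contrasts are null-calibrated, antisymmetric and validated", {
  design <- two_cond_design()
  m <- matrix(rep(c(24.0, 24.5, 25.0), 2), 1, 6, byrow = TRUE,
              dimnames = list("p1", design$sample_id))
  cv <- flat_curves(design, rho = -50)
  fit <- fit_dropout_model(as_lfq_tbl(m, "log2"), design, curves = cv)
  res <- test_contrast(fit, c("A", "B"))
  expect_lt(abs(res$delta), 1e-8)
  expect_gt(res$p, 0.99)

  set.seed(37)
  m2 <- matrix(rnorm(120, 25, 0.5), 20, 6,
               dimnames = list(paste0("p", 1:20), design$sample_id))
  m2[sample(length(m2), 20)] <- NA
  fit2 <- fit_dropout_model(as_lfq_tbl(m2, "log2"), design,
                            curves = flat_curves(design, rho = 24))
  ab <- test_contrast(fit2, c("A", "B"))
  ba <- test_contrast(fit2, c("B", "A"))
  expect_lt(max(abs(ab$delta + ba$delta)), 1e-9)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  expect_error(test_contrast(fit2, c("A", "A")), "itself")
  expect_error(test_contrast(fit2, c("A", "Z")), "absent")
})

test_that("planted effects are recovered near their true size", {
  truth <- generate_interactome_truth(
    n_background = 500, n_interactors = 100, n_decoys = 0,
    isoforms = "PRDX1", cys_dependent_fraction = 1, effect_size = 3,
    multi_bind_fraction = 0, low_peptide_fraction = 0, seed = 13
  )
  design <- prdx_design(isoforms = "PRDX1")
  sim <- simulate_lfq_experiment(truth, design, seed = 13)
  ct <- genotype_contrasts(sim$lfq, design, c("WT", "CPRS"))
  planted <- ct$delta[ct$protein_id %in% truth$protein_id[truth$cys_dependent]]
  expect_equal(mean(planted), 3, tolerance = 0.3 / 3)
})

test_that("tidy and glance summarize fits coherently", {
  design <- two_cond_design()
  set.seed(38)
  m <- matrix(rnorm(36, 25, 0.5), 6, 6,
              dimnames = list(paste0("p", 1:6), design$sample_id))
  fit <- fit_dropout_model(as_lfq_tbl(m, "log2"), design,
                           curves = flat_curves(design, rho = -50))
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_setequal(unique(td$condition), c("A", "B"))
  gl <- glance(fit)
  expect_equal(gl$n_proteins, 6)
  expect_equal(gl$prop_converged, 1)
})
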