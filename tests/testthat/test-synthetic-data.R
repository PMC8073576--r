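test_that("truth generation respects counts, classes and determinism", {
  t0 <- generate_interactome_truth(n_background = 30, n_interactors = 0,
                                   n_decoys = 0, seed = 1)
  expect_equal(nrow(t0), 30)
  expect_true(all(lengths(t0$binds_isoforms) == 0))
  expect_true(all(t0$mechanism == "none"))

  t1 <- generate_interactome_truth(n_background = 40, n_interactors = 25,
                                   n_decoys = 6, seed = 2)
  t1b <- generate_interactome_truth(n_background = 40, n_interactors = 25,
                                    n_decoys = 6, seed = 2)
  expect_identical(t1, t1b)
  expect_equal(nrow(t1), 71)
  expect_equal(sum(t1$is_decoy), 6)
  # decoys never bind and carry REV/CON prefixes
  expect_true(all(lengths(t1$binds_isoforms[t1$is_decoy]) == 0))
  expect_true(all(grepl("^(REV|CON)__", t1$protein_id[t1$is_decoy])))
  # mechanism only for cysteine-dependent interactors
  expect_true(all(t1$cys_dependent[t1$mechanism != "none"]))
  expect_true(all(t1$mechanism[!t1$cys_dependent] == "none"))

  expect_error(generate_interactome_truth(n_background = -1, seed = 1),
               "non-negative")
  expect_error(
    generate_interactome_truth(mechanism_mix = c(SOH = 0.8, SS = 0.4),
                               seed = 1),
    "at most 1"
  )
})

test_that("mechanism mix is realized within exact binomial bounds", {
  truth <- generate_interactome_truth(
    n_background = 0, n_interactors = 1000, n_decoys = 0,
    cys_dependent_fraction = 1, mechanism_mix = c(SOH = 0.7, SS = 0.3),
    seed = 7
  )
  n_soh <- sum(truth$mechanism == "SOH")
  # central 99% region of Binomial(1000, 0.7)
  expect_gte(n_soh, qbinom(0.005, 1000, 0.7))
  expect_lte(n_soh, qbinom(0.995, 1000, 0.7))
})

test_that("simulated intensities place effects by mechanism and genotype", {
  truth <- tibble::tibble(
    protein_id = c("SOH1", "SS1", "NCD1", "BG1"),
    gene_name = paste0("G", 1:4),
    baseline = c(25, 25, 25, 25),
    binds_isoforms = list("PRDX2", "PRDX2", "PRDX2", character(0)),
    cys_dependent = c(TRUE, TRUE, FALSE, FALSE),
    mechanism = c("SOH", "SS", "none", "none"),
    effect_size = c(4, 4, 4, 0),
    is_decoy = FALSE,
    decoy_type = NA_character_,
    n_unique_peptides = 5L,
    redox_sensitive = FALSE
  )
  design <- prdx_design(isoforms = c("PRDX1", "PRDX2"))
  sim <- simulate_lfq_experiment(truth, design,
                                 dropout = dropout_spec(rho = -Inf),
                                 noise_sd = 1e-4, seed = 3)
  y <- as_intensity_matrix(sim$lfq, samples = design$sample_id)
  mean_of <- function(p, iso, geno) {
    mean(y[p, design$isoform == iso & design$genotype == geno])
  }
  tol <- 0.01
  # SOH: enriched with WT and CRS baits of its isoform, not CPRS
  expect_equal(mean_of("SOH1", "PRDX2", "WT"), 29, tolerance = tol)
  expect_equal(mean_of("SOH1", "PRDX2", "CRS"), 29, tolerance = tol)
  expect_equal(mean_of("SOH1", "PRDX2", "CPRS"), 25, tolerance = tol)
  # SS: WT only
  expect_equal(mean_of("SS1", "PRDX2", "WT"), 29, tolerance = tol)
  expect_equal(mean_of("SS1", "PRDX2", "CRS"), 25, tolerance = tol)
  # non-cysteine-dependent: all genotypes of its isoform
  expect_equal(mean_of("NCD1", "PRDX2", "CPRS"), 29, tolerance = tol)
  # never on the other isoform's baits
  expect_equal(mean_of("SOH1", "PRDX1", "WT"), 25, tolerance = tol)
  # background flat
  expect_equal(mean_of("BG1", "PRDX2", "WT"), 25, tolerance = tol)
})

test_that("dropout realizes its target and follows the probit curve", {
  truth <- generate_interactome_truth(n_background = 5000, n_interactors = 0,
                                      n_decoys = 0, low_peptide_fraction = 0,
                                      seed = 4)
  design <- prdx_design(isoforms = "PRDX1")
  sim <- simulate_lfq_experiment(truth, design, seed = 4)
  expect_equal(sim$dropout$realized_missing, 0.34, tolerance = 0.02)

  # per-intensity-bin missing fraction tracks Phi((rho - y)/zeta)
  lat <- as_intensity_matrix(sim$latent, samples = design$sample_id)
  obs <- as_intensity_matrix(sim$lfq, samples = design$sample_id)
  y <- as.vector(lat)
  missing <- is.na(as.vector(obs))
  rho <- sim$dropout$rho[1]
  zeta <- sim$dropout$zeta[1]
  bins <- cut(y, breaks = quantile(y, seq(0, 1, 0.1)), include.lowest = TRUE)
  emp <- tapply(missing, bins, mean)
  theo <- tapply(pnorm((rho - y) / zeta), bins, mean)
  expect_lt(max(abs(emp - theo)), 0.02)
  # monotone non-increasing in intensity (within binomial noise)
  expect_true(all(diff(emp) < 0.02))

  # disabled dropout leaves no missing cells
  sim0 <- simulate_lfq_experiment(truth[1:50, ], design,
                                  dropout = dropout_spec(rho = -Inf),
                                  seed = 4)
  expect_false(anyNA(sim0$lfq$intensity))

  # bitwise reproducibility
  sim_b <- simulate_lfq_experiment(truth, design, seed = 4)
  expect_identical(sim$lfq, sim_b$lfq)

  expect_error(simulate_lfq_experiment(truth, design, noise_sd = 0),
               "positive")
})

test_that("zero planted effect leaves WT and CPRS exchangeable across seeds", {
  pvals <- vapply(1:12, function(s) {
    sim <- small_null_sim(n = 120, seed = 400 + s)
    d <- dplyr::inner_join(sim$lfq, sim$design, by = "sample_id")
    dm <- d |>
      dplyr::filter(.data$genotype %in% c("WT", "CPRS")) |>
      dplyr::summarise(m = mean(.data$intensity, na.rm = TRUE),
                       .by = c("protein_id", "genotype")) |>
      tidyr::pivot_wider(names_from = "genotype", values_from = "m") |>
      dplyr::filter(is.finite(.data$WT), is.finite(.data$CPRS),
                    .data$WT != .data$CPRS)
    binom.test(sum(dm$WT > dm$CPRS), nrow(dm))$p.value
  }, double(1))
  # the per-protein sign of the WT - CPRS mean difference is a fair coin:
  # no seed should show a wildly significant imbalance, and the p-values
  # should not all bunch at 1 either
  expect_gt(min(pvals), 0.01 / 12)
  expect_gt(mean(pvals < 0.9), 0.25)
})

test_that("generated sequences are uniform, cysteine-bearing, deterministic", {
  truth <- generate_interactome_truth(n_background = 350, n_interactors = 0,
                                      n_decoys = 0, seed = 5)
  seqs <- generate_protein_sequences(truth, seed = 5)
  expect_identical(seqs, generate_protein_sequences(truth, seed = 5))
  expect_true(all(grepl("C", seqs$sequence)))
  res <- unlist(strsplit(seqs$sequence, ""))
  expect_gt(length(res), 1e5)
  expect_gt(chisq.test(table(res))$p.value, 0.01)
})

test_that("planted flanking residues reach their configured frequency", {
  truth <- generate_interactome_truth(
    n_background = 0, n_interactors = 400, n_decoys = 0,
    isoforms = "PRDX1", multi_bind_fraction = 0, seed = 6
  )
  spec <- data.frame(isoform = "PRDX1", offset = -3, residue = "R",
                     fraction = 0.5)
  seqs <- generate_protein_sequences(truth, motif_spec = spec, seed = 6)
  w <- extract_cys_windows(seqs)
  at <- substr(w$window, 2, 2)  # offset -3 of the 9-mer
  ok <- at != "-"
  n <- sum(ok)
  k <- sum(at[ok] == "R")
  # planted fraction + background usage of R at unplanted positions; the
  # plant skips positions occupied by another cysteine, so allow the exact
  # binomial band a small downward widening
  expected <- 0.5 + 0.5 * (1 / 20)
  expect_gte(k, qbinom(0.005, n, expected) - ceiling(0.03 * n))
  expect_lte(k, qbinom(0.995, n, expected))

  expect_error(
    generate_protein_sequences(truth,
                               motif_spec = data.frame(isoform = "PRDX1",
                                                       offset = 5,
                                                       residue = "R",
                                                       fraction = 0.5),
                               seed = 6),
    "-4..4"
  )
})

test_that("compartment tables honor planted biases and degenerate inputs", {
  truth <- generate_interactome_truth(n_background = 50, n_interactors = 20,
                                      n_decoys = 0, seed = 8)
  single <- generate_compartment_table(truth, compartments = "Cytosol",
                                       seed = 8)
  expect_true(all(single$compartment == "Cytosol"))
  expect_error(generate_compartment_table(truth, compartments = character(0)),
               "non-empty")
  two <- generate_compartment_table(truth, seed = 9)
  expect_identical(two, generate_compartment_table(truth, seed = 9))
})

test_that("truth serialization round-trips losslessly", {
  truth <- generate_interactome_truth(n_background = 15, n_interactors = 8,
                                      n_decoys = 3, seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(as.data.frame(truth), as.data.frame(back), tolerance = 1e-12)
})
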