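# Planted-truth generator: interactome truth, LFQ intensities with
# intensity-dependent dropout, protein sequences, compartment annotations.

#' Generate a planted interactome ground truth
#'
#' Draws a protein universe for a pull-down screen: background (non-binding)
#' proteins, interactors bound to one or more bait isoforms, and decoy rows
#' (reverse hits / contaminants) that exercise the table filters. Interactors
#' are marked cysteine-dependent or not; cysteine-dependent ones carry a
#' binding mechanism: `SOH` (binds the sulfenylated peroxidatic cysteine, so
#' also recovered by the resolving-cysteine mutant bait) or `SS` (requires the
#' catalytic disulfide, wild-type bait only).
#'
#' @param n_background Number of non-binding proteins.
#' @param n_interactors Number of bait-binding proteins.
#' @param n_decoys Number of decoy rows (split between reverse hits and
#'   contaminants).
#' @param isoforms Bait isoforms interactors may bind.
#' @param cys_dependent_fraction Probability that an interactor binds in a
#'   cysteine-dependent manner.
#' @param mechanism_mix Named numeric, proportions of `SOH` and `SS` among
#'   cysteine-dependent interactors; must be non-negative, sum at most 1,
#'   and is renormalized if it sums below 1.
#' @param effect_size Log2 enrichment of binding over non-binding genotypes.
#' @param multi_bind_fraction Fraction of interactors binding two isoforms.
#' @param baseline_mean,baseline_sd Log2-normal baseline abundance parameters
#'   (typical LFQ dynamic range).
#' @param binder_redox_fraction,background_redox_fraction Probability that an
#'   interactor (resp. background protein) is flagged redox-sensitive in the
#'   simulated reference list.
#' @param low_peptide_fraction Fraction of non-decoy proteins given fewer than
#'   3 unique peptides, to exercise the peptide-count filter.
#' @param seed Integer seed; one RNG stream per generator op is derived from
#'   it, so reruns with the same seed reproduce the truth exactly.
#' @return A tibble of class `prx_truth`, one row per protein, with columns
#'   `protein_id`, `gene_name`, `baseline`, `binds_isoforms` (list column),
#'   `cys_dependent`, `mechanism`, `effect_size`, `is_decoy`, `decoy_type`,
#'   `n_unique_peptides` and `redox_sensitive`.
#' @examples
#' truth <- generate_interactome_truth(n_background = 50, n_interactors = 10,
#'                                     n_decoys = 4, seed = 1)
#' table(truth$mechanism)
#' @export
generate_interactome_truth <- function(n_background = 800L,
                                       n_interactors = 200L,
                                       n_decoys = 20L,
                                       isoforms = PRDX_ISOFORMS,
                                       cys_dependent_fraction = 0.8,
                                       mechanism_mix = c(SOH = 0.7, SS = 0.3),
                                       effect_size = 4,
                                       multi_bind_fraction = 0.15,
                                       baseline_mean = 25,
                                       baseline_sd = 3,
                                       binder_redox_fraction = 0.8,
                                       background_redox_fraction = 0.13,
                                       low_peptide_fraction = 0.05,
                                       seed = 1L) {
  counts <- c(n_background = n_background, n_interactors = n_interactors,
              n_decoys = n_decoys)
  if (any(counts < 0)) {
    abort("Protein class counts must be non-negative.")
  }
  if (!all(c("SOH", "SS") %in% names(mechanism_mix)) ||
      any(mechanism_mix < 0) || sum(mechanism_mix) > 1 + 1e-8) {
    abort("`mechanism_mix` needs non-negative SOH and SS entries summing to at most 1.")
  }
  if (effect_size < 0) {
    abort("`effect_size` must be non-negative.")
  }
  mech_p <- mechanism_mix[c("SOH", "SS")] / sum(mechanism_mix[c("SOH", "SS")])

  local_seed(seed, SEED_OFFSET[["truth"]], {
    n_total <- n_background + n_interactors + n_decoys
    id <- sprintf("P%05d", seq_len(n_total))
    class <- rep(c("background", "interactor", "decoy"),
                 times = c(n_background, n_interactors, n_decoys))

    decoy_type <- rep(NA_character_, n_total)
    is_decoy <- class == "decoy"
    if (n_decoys > 0) {
      decoy_type[is_decoy] <- sample(c("REV", "CON"), n_decoys, replace = TRUE)
      id[is_decoy] <- paste0(decoy_type[is_decoy], "__", id[is_decoy])
    }

    binds <- vector("list", n_total)
    binds[] <- list(character(0))
    idx_int <- which(class == "interactor")
    if (length(idx_int) > 0) {
      n_bind <- 1L + rbinom(length(idx_int), 1L,
                            min(multi_bind_fraction, 1))
      n_bind <- pmin(n_bind, length(isoforms))
      binds[idx_int] <- lapply(n_bind, function(k) {
        sort(sample(isoforms, k))
      })
    }

    cys_dep <- rep(FALSE, n_total)
    cys_dep[idx_int] <- runif(length(idx_int)) < cys_dependent_fraction
    mechanism <- rep("none", n_total)
    n_cd <- sum(cys_dep)
    if (n_cd > 0) {
      mechanism[cys_dep] <- sample(c("SOH", "SS"), n_cd, replace = TRUE,
                                   prob = mech_p)
    }

    n_pep <- 3L + rpois(n_total, 5L)
    low <- runif(n_total) < low_peptide_fraction & !is_decoy
    n_pep[low] <- sample(0:2, sum(low), replace = TRUE)

    redox <- runif(n_total) < ifelse(class == "interactor",
                                     binder_redox_fraction,
                                     background_redox_fraction)
    redox[is_decoy] <- FALSE

    out <- tibble(
      protein_id = id,
      gene_name = paste0("GN_", sub("^(REV|CON)__", "", id)),
      baseline = rnorm(n_total, baseline_mean, baseline_sd),
      binds_isoforms = binds,
      cys_dependent = cys_dep,
      mechanism = mechanism,
      effect_size = ifelse(class == "interactor", effect_size, 0),
      is_decoy = is_decoy,
      decoy_type = decoy_type,
      n_unique_peptides = as.integer(n_pep),
      redox_sensitive = redox
    )
    class(out) <- c("prx_truth", class(out))
    out
  })
}

#' Specify a sigmoidal dropout model
#'
#' A cell with true log2 intensity `y` is missing with probability
#' `pnorm((rho - y) / zeta)`: a probit sigmoid falling with intensity. `rho`
#' is the intensity at 50% dropout, `zeta` the curve width. Either fix `rho`
#' directly (`-Inf` disables dropout) or give `target_missing` and let the
#' simulator solve for the `rho` that realizes that mean missing fraction.
#'
#' @param rho Intensity (log2) at 50% dropout; `NULL` to solve from
#'   `target_missing`.
#' @param zeta Dropout curve scale (log2 units, > 0).
#' @param target_missing Desired mean missing fraction in `[0, 1)`.
#' @return A list of class `prx_dropout_spec`.
#' @export
dropout_spec <- function(rho = NULL, zeta = 1, target_missing = 0.34) {
  if (any(zeta <= 0)) {
    abort("`zeta` must be positive.")
  }
  if (is.null(rho)) {
    if (is.null(target_missing) || target_missing < 0 || target_missing >= 1) {
      abort("Give `rho`, or `target_missing` in [0, 1).")
    }
  }
  structure(
    list(rho = rho, zeta = zeta, target_missing = target_missing),
    class = "prx_dropout_spec"
  )
}

# Solve the dropout midpoint rho so that the expected missing fraction over
# the realized latent intensities equals `target`.
solve_dropout_rho <- function(y, zeta, target) {
  if (target <= 0) {
    return(-Inf)
  }
  f <- function(r) mean(pnorm((r - y) / zeta)) - target
  uniroot(f, lower = min(y) - 10 * max(zeta), upper = max(y) + 10 * max(zeta),
          tol = 1e-9)$root
}

#' Simulate an LFQ pull-down experiment from a planted truth
#'
#' Draws one log2 intensity per (protein, sample): baseline plus the
#' genotype-appropriate binding effect plus Gaussian replicate noise, then
#' censors each cell by the sigmoidal dropout curve. Effect placement encodes
#' the binding biology: `SOH`-mechanism interactors are enriched in `WT` and
#' `CRS` baits of their isoform(s), `SS`-mechanism interactors in `WT` only,
#' and non-cysteine-dependent binders in all genotypes of their isoform(s).
#'
#' @param truth Tibble from [generate_interactome_truth()].
#' @param design Tibble from [prdx_design()].
#' @param dropout A [dropout_spec()].
#' @param noise_sd Replicate noise standard deviation, log2 units (> 0).
#' @param seed Integer seed.
#' @return A list of class `prx_lfq_sim` with elements `lfq` (long log2-scale
#'   tibble, `NA` = dropped out), `latent` (long tibble of pre-dropout
#'   intensities), `proteins` (record table for the proteinGroups writer),
#'   `truth`, `design`, and `dropout` (realized `rho`, `zeta` per sample and
#'   mean missing fraction).
#' @examples
#' truth <- generate_interactome_truth(n_background = 40, n_interactors = 10,
#'                                     n_decoys = 2, seed = 1)
#' sim <- simulate_lfq_experiment(truth, prdx_design(), seed = 1)
#' sim$dropout$realized_missing
#' @export
simulate_lfq_experiment <- function(truth,
                                    design = prdx_design(),
                                    dropout = dropout_spec(),
                                    noise_sd = 0.5,
                                    seed = 1L) {
  check_design(design)
  if (noise_sd <= 0) {
    abort("`noise_sd` must be positive.")
  }
  has_pair <- design |>
    distinct(.data$isoform, .data$genotype) |>
    summarise(ok = any(.data$genotype == "WT") && any(.data$genotype == "CPRS"),
              .by = "isoform")
  if (!any(has_pair$ok)) {
    abort("`design` must cover at least one isoform with both WT and CPRS baits.")
  }
  n_samp <- nrow(design)
  zeta <- rep_len(dropout$zeta, n_samp)

  local_seed(seed, SEED_OFFSET[["lfq"]], {
    n_prot <- nrow(truth)
    mu <- matrix(truth$baseline, nrow = n_prot, ncol = n_samp,
                 dimnames = list(truth$protein_id, design$sample_id))
    for (i in seq_len(n_prot)) {
      iso <- truth$binds_isoforms[[i]]
      if (length(iso) == 0) next
      hit <- design$isoform %in% iso
      if (truth$cys_dependent[i]) {
        geno <- if (truth$mechanism[i] == "SOH") c("WT", "CRS") else "WT"
        hit <- hit & design$genotype %in% geno
      }
      mu[i, hit] <- mu[i, hit] + truth$effect_size[i]
    }
    y <- mu + matrix(rnorm(n_prot * n_samp, 0, noise_sd), n_prot, n_samp)

    rho <- dropout$rho
    if (is.null(rho)) {
      rho <- solve_dropout_rho(as.vector(y), mean(zeta),
                               dropout$target_missing)
    }
    rho <- rep_len(rho, n_samp)
    p_miss <- pnorm((matrix(rho, n_prot, n_samp, byrow = TRUE) - y) /
                      matrix(zeta, n_prot, n_samp, byrow = TRUE))
    miss <- matrix(runif(n_prot * n_samp), n_prot, n_samp) < p_miss
    obs <- y
    obs[miss] <- NA_real_

    proteins <- tibble(
      protein_id = truth$protein_id,
      gene_name = truth$gene_name,
      n_unique_peptides = truth$n_unique_peptides,
      reverse = !is.na(truth$decoy_type) & truth$decoy_type == "REV",
      contaminant = !is.na(truth$decoy_type) & truth$decoy_type == "CON"
    )

    structure(
      list(
        lfq = as_lfq_tbl(obs, scale = "log2"),
        latent = as_lfq_tbl(y, scale = "log2"),
        proteins = proteins,
        truth = truth,
        design = design,
        dropout = list(rho = rho, zeta = zeta,
                       realized_missing = mean(miss))
      ),
      class = "prx_lfq_sim"
    )
  })
}

#' Generate protein sequences with optional planted cysteine-flanking motifs
#'
#' Sequences use the 20 standard amino acids uniformly (so the flanking
#' background is flat) and every protein is guaranteed at least one cysteine.
#' A motif spec plants residues at fixed offsets from cysteines in the
#' binders of chosen isoforms, e.g. "R at offset -3 in half the windows of
#' PRDX1 binders".
#'
#' @param truth Tibble from [generate_interactome_truth()].
#' @param motif_spec `NULL`, or a data frame with columns `isoform`, `offset`
#'   (in `-4..4`, not 0), `residue` and `fraction` (probability the residue is
#'   planted at that offset of each cysteine window of a binder of that
#'   isoform).
#' @param length_range Integer range of sequence lengths (min 9).
#' @param seed Integer seed.
#' @return Tibble with `protein_id` and `sequence`.
#' @export
generate_protein_sequences <- function(truth,
                                       motif_spec = NULL,
                                       length_range = c(150L, 500L),
                                       seed = 1L) {
  if (length_range[1] < 9) {
    abort("Sequences must be at least 9 residues long.")
  }
  if (!is.null(motif_spec)) {
    motif_spec <- as_tibble(motif_spec)
    need <- c("isoform", "offset", "residue", "fraction")
    if (!all(need %in% names(motif_spec))) {
      abort("`motif_spec` needs columns isoform, offset, residue, fraction.")
    }
    if (any(motif_spec$offset == 0) || any(abs(motif_spec$offset) > 4)) {
      abort("Motif offsets must lie in -4..4 and cannot be 0 (the cysteine).")
    }
    if (!all(motif_spec$residue %in% AA_ALPHABET)) {
      abort("Motif residues must be standard amino acids.")
    }
  }

  local_seed(seed, SEED_OFFSET[["sequences"]], {
    n <- nrow(truth)
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      s <- sample(AA_ALPHABET, L, replace = TRUE)
      if (!any(s == "C")) {
        s[sample(seq(5, L - 4), 1)] <- "C"
      }
      paste(s, collapse = "")
    }, character(1))

    if (!is.null(motif_spec)) {
      for (i in seq_len(n)) {
        iso <- truth$binds_isoforms[[i]]
        rules <- motif_spec[motif_spec$isoform %in% iso, , drop = FALSE]
        if (nrow(rules) == 0) next
        s <- strsplit(seqs[i], "")[[1]]
        cys <- which(s == "C")
        for (r in seq_len(nrow(rules))) {
          pos <- cys + rules$offset[r]
          ok <- pos >= 1 & pos <= length(s)
          pos <- pos[ok]
          plant <- pos[runif(length(pos)) < rules$fraction[r]]
          plant <- plant[s[plant] != "C"]  # keep cysteine positions intact
          s[plant] <- rules$residue[r]
        }
        seqs[i] <- paste(s, collapse = "")
      }
    }
    tibble(protein_id = truth$protein_id, sequence = seqs)
  })
}

#' Generate a subcellular compartment annotation table
#'
#' Assigns one compartment per protein. Background proteins draw uniformly
#' from `compartments`; binders of an isoform listed in `bias` draw that
#' compartment with probability multiplied by `fold` (then renormalized),
#' planting a localization enrichment the downstream analysis should recover.
#'
#' @param truth Tibble from [generate_interactome_truth()].
#' @param compartments Non-empty character vector of compartment labels.
#' @param bias `NULL`, or data frame with columns `isoform`, `compartment`,
#'   `fold`.
#' @param seed Integer seed.
#' @return Tibble with `protein_id` and `compartment`.
#' @export
generate_compartment_table <- function(truth,
                                       compartments = c("Cytosol",
                                                        "Mitochondria",
                                                        "Nucleus",
                                                        "Secretory"),
                                       bias = NULL,
                                       seed = 1L) {
  if (length(compartments) == 0) {
    abort("`compartments` must be non-empty.")
  }
  if (!is.null(bias)) {
    bias <- as_tibble(bias)
    if (!all(c("isoform", "compartment", "fold") %in% names(bias))) {
      abort("`bias` needs columns isoform, compartment, fold.")
    }
    if (!all(bias$compartment %in% compartments)) {
      abort("Biased compartments must appear in `compartments`.")
    }
  }
  k <- length(compartments)
  local_seed(seed, SEED_OFFSET[["compartments"]], {
    comp <- vapply(seq_len(nrow(truth)), function(i) {
      p <- rep(1 / k, k)
      if (!is.null(bias)) {
        iso <- truth$binds_isoforms[[i]]
        hit <- bias[bias$isoform %in% iso, , drop = FALSE]
        for (r in seq_len(nrow(hit))) {
          j <- match(hit$compartment[r], compartments)
          p[j] <- p[j] * hit$fold[r]
        }
        p <- p / sum(p)
      }
      sample(compartments, 1, prob = p)
    }, character(1))
    tibble(protein_id = truth$protein_id, compartment = comp)
  })
}

#' Serialize / restore a planted truth table
#'
#' JSON round trip for the ground-truth table, so a simulated experiment's
#' truth can be archived next to its outputs and reloaded losslessly.
#'
#' @param truth Tibble from [generate_interactome_truth()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_truth()` returns the truth tibble.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(as.data.frame(truth), path, auto_unbox = FALSE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(raw)
  out$binds_isoforms <- lapply(out$binds_isoforms, function(x) {
    if (is.null(x) || length(x) == 0) character(0) else as.character(x)
  })
  out$decoy_type <- as.character(out$decoy_type)
  out$n_unique_peptides <- as.integer(out$n_unique_peptides)
  class(out) <- c("prx_truth", class(out))
  out
}
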