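# End-to-end orchestration: config validation, stage sequencing, outputs.

#' Build and validate a pipeline configuration
#'
#' Exactly one of `synthetic` (generator settings) or `input` (file paths)
#' must be given. All thresholds default to the analysis' standard gates:
#' log2 fold change > 1 with p < 0.05 for cysteine dependency (raw p), BH
#' q < 0.05 for isoform specificity, 100 label permutations at an included
#' fraction of 5%, 100 sequence shuffles, 10-fold selection for
#' localization, and 9-mer cysteine windows.
#'
#' @param synthetic `NULL`, or a list of overrides for
#'   [generate_interactome_truth()] / [simulate_lfq_experiment()] /
#'   [generate_protein_sequences()] / [generate_compartment_table()]
#'   (`n_background`, `n_interactors`, `n_decoys`, `effect_size`,
#'   `noise_sd`, `target_missing`, `mechanism_mix`, `motif_spec`,
#'   `compartment_bias`, `n_replicates`, ...).
#' @param input `NULL`, or a list of paths: `protein_groups` (required),
#'   optional `design` (TSV with sample_id, isoform, genotype, replicate),
#'   `fasta`, `reference`, `compartments`.
#' @param thresholds,calibration,sequence Named lists of overrides.
#' @param seed Top-level integer seed fanned out to all stochastic stages.
#' @return A validated list of class `prx_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            thresholds = list(), calibration = list(),
                            sequence = list(), seed = 1L) {
  if (is.null(synthetic) == is.null(input)) {
    abort("Exactly one of `synthetic` or `input` must be given.")
  }
  thresholds <- modifyList(
    list(delta_min = 1, alpha = 0.05, p_mode_cys = "raw",
         p_mode_isoform = "bh", fold_min = 10),
    thresholds
  )
  calibration <- modifyList(list(n_perm = 100L, alpha = 0.05), calibration)
  sequence <- modifyList(
    list(n_shuffles = 100L, half_width = 4L, min_support = 10L,
         p_fix = 1e-4),
    sequence
  )
  num <- c(thresholds$delta_min, thresholds$alpha, thresholds$fold_min,
           calibration$n_perm, calibration$alpha, sequence$n_shuffles,
           sequence$half_width, sequence$min_support, sequence$p_fix)
  if (any(num <= 0 & c(FALSE, rep(TRUE, length(num) - 1))) ||
      thresholds$delta_min < 0) {
    abort("All thresholds must be positive (delta_min may be zero).")
  }
  if (!is.null(input) && is.null(input$protein_groups)) {
    abort("`input` must include a `protein_groups` path.")
  }
  structure(
    list(synthetic = synthetic, input = input, thresholds = thresholds,
         calibration = calibration, sequence = sequence,
         seed = as.integer(seed)),
    class = "prx_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching [pipeline_config()]
#'   arguments.
#' @return A validated `prx_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    synthetic = y$synthetic, input = y$input,
    thresholds = y$thresholds %||% list(),
    calibration = y$calibration %||% list(),
    sequence = y$sequence %||% list(),
    seed = y$seed %||% 1L
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)), parent = e)
  })
}

parse_design_from_samples <- function(sample_ids) {
  parts <- strsplit(sample_ids, "_", fixed = TRUE)
  ok <- lengths(parts) == 3
  if (!all(ok)) {
    abort("Cannot parse (isoform, genotype, replicate) from sample names; provide a design table.")
  }
  tibble(
    sample_id = sample_ids,
    isoform = vapply(parts, `[[`, character(1), 1),
    genotype = vapply(parts, `[[`, character(1), 2),
    replicate = as.integer(vapply(parts, `[[`, character(1), 3))
  ) |>
    mutate(condition = paste(.data$isoform, .data$genotype, sep = "_"))
}

acquire_synthetic <- function(syn, seed) {
  truth_args <- syn[intersect(names(syn), names(formals(generate_interactome_truth)))]
  truth_args$seed <- seed
  truth <- do.call(generate_interactome_truth, truth_args)
  design <- prdx_design(
    isoforms = syn$isoforms %||% PRDX_ISOFORMS,
    n_replicates = syn$n_replicates %||% 3L
  )
  sim <- simulate_lfq_experiment(
    truth, design,
    dropout = dropout_spec(
      rho = syn$rho,
      zeta = syn$zeta %||% 1,
      target_missing = syn$target_missing %||% 0.34
    ),
    noise_sd = syn$noise_sd %||% 0.5,
    seed = seed
  )
  sequences <- generate_protein_sequences(truth,
                                          motif_spec = syn$motif_spec,
                                          seed = seed)
  compartments <- generate_compartment_table(truth,
                                             bias = syn$compartment_bias,
                                             seed = seed)
  lfq_raw <- sim$lfq
  lfq_raw$intensity <- 2^lfq_raw$intensity
  lfq_raw <- set_lfq_scale(lfq_raw, "raw")
  list(
    proteins = sim$proteins,
    lfq_raw = lfq_raw,
    design = design,
    sequences = sequences,
    compartments = compartments,
    reference_ids = truth$protein_id[truth$redox_sensitive],
    truth = truth,
    sim = sim
  )
}

acquire_input <- function(inp) {
  pg <- read_protein_groups(inp$protein_groups)
  design <- if (!is.null(inp$design)) {
    d <- readr::read_tsv(inp$design, show_col_types = FALSE, progress = FALSE)
    check_design(d)
    if (!"condition" %in% names(d)) {
      d$condition <- paste(d$isoform, d$genotype, sep = "_")
    }
    d
  } else {
    parse_design_from_samples(unique(pg$lfq$sample_id))
  }
  list(
    proteins = pg$proteins,
    lfq_raw = pg$lfq,
    design = design,
    sequences = if (!is.null(inp$fasta)) read_fasta(inp$fasta) else NULL,
    compartments = if (!is.null(inp$compartments)) {
      readr::read_tsv(inp$compartments, show_col_types = FALSE,
                      progress = FALSE)
    } else {
      NULL
    },
    reference_ids = if (!is.null(inp$reference)) {
      read_reference_list(inp$reference)
    } else {
      NULL
    },
    truth = NULL,
    sim = NULL
  )
}

#' Run the full interactome analysis pipeline
#'
#' Stage order: acquire (read or generate) -> filter -> log2 -> quantile
#' normalization -> dropout curves -> contrasts (WT vs CPRS, CRS vs CPRS,
#' WT vs CRS, isoform vs rest) -> permutation calibration ->
#' classifications, mechanism split and set intersections -> redox and
#' localization enrichment -> sequence analyses (skipped with a notice if
#' no sequences are available). With synthetic input, a truth-recovery
#' report (sensitivity, empirical FDR, mechanism fractions) is added.
#'
#' @param config A `prx_config` from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML config.
#' @param out_dir Optional directory; when given, every stage output is
#'   written there as TSV/JSON along with a reproducibility manifest.
#' @return A list with all stage results, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  if (!inherits(config, "prx_config")) {
    abort("`config` must be a prx_config or a YAML path.")
  }
  th <- config$thresholds
  seed <- config$seed

  data <- run_stage("acquire", {
    if (!is.null(config$synthetic)) {
      acquire_synthetic(config$synthetic, seed)
    } else {
      acquire_input(config$input)
    }
  })

  filtered <- run_stage("filter", {
    filter_proteins(data$proteins, data$lfq_raw, data$design)
  })
  lfq <- run_stage("log2", log2_transform(filtered$lfq))
  lfq <- run_stage("quantile_normalize", quantile_normalize(lfq))
  curves <- run_stage("dropout_curves", {
    estimate_dropout_curves(lfq, data$design)
  })

  contrasts <- run_stage("contrasts", {
    list(
      wt_vs_cprs = genotype_contrasts(lfq, data$design, c("WT", "CPRS"),
                                      curves = curves),
      crs_vs_cprs = genotype_contrasts(lfq, data$design, c("CRS", "CPRS"),
                                       curves = curves),
      wt_vs_crs = genotype_contrasts(lfq, data$design, c("WT", "CRS"),
                                     curves = curves),
      isoform_vs_rest = if (length(unique(data$design$isoform)) > 1) {
        isoform_specificity_contrasts(lfq, data$design, curves = curves)
      } else {
        NULL
      }
    )
  })

  calibration <- run_stage("calibration", {
    randomize_labels_fdr(lfq, data$design,
                         n_perm = config$calibration$n_perm,
                         alpha = config$calibration$alpha,
                         curves = curves, seed = seed)
  })

  classifications <- run_stage("classify", {
    cys_dep <- classify_cysteine_dependent(
      contrasts$wt_vs_cprs, delta_min = th$delta_min, alpha = th$alpha,
      p_mode = th$p_mode_cys
    )
    cp_dep <- classify_cysteine_dependent(
      contrasts$crs_vs_cprs, delta_min = th$delta_min, alpha = th$alpha,
      p_mode = th$p_mode_cys
    )
    iso_spec <- if (!is.null(contrasts$isoform_vs_rest)) {
      classify_isoform_specific(
        contrasts$isoform_vs_rest, delta_min = th$delta_min,
        alpha = th$alpha, p_mode = th$p_mode_isoform
      )
    } else {
      NULL
    }
    isoforms <- unique(cys_dep$isoform)
    # For the mechanism partition, CRS binding is judged on the estimated
    # fold change alone: failing the significance gate reflects lack of
    # power, not evidence of absence, and would inflate the relay (SS) group.
    crs_tbl <- contrasts$crs_vs_cprs
    mechanisms <- purrr::map(setNames(isoforms, isoforms), function(iso) {
      classify_mechanism(
        cys_dep$protein_id[cys_dep$isoform == iso],
        crs_tbl$protein_id[crs_tbl$isoform == iso &
                             crs_tbl$delta > th$delta_min]
      )
    })
    cys_sets <- purrr::map(setNames(isoforms, isoforms), function(iso) {
      cys_dep$protein_id[cys_dep$isoform == iso]
    })
    list(
      cys_dependent = cys_dep,
      cp_dependent = cp_dep,
      isoform_specific = iso_spec,
      mechanisms = mechanisms,
      intersections = if (length(cys_sets) > 0) {
        set_intersections(cys_sets)
      } else {
        NULL
      }
    )
  })

  enrichment <- run_stage("enrichment", {
    cys_sets <- split(classifications$cys_dependent$protein_id,
                      classifications$cys_dependent$isoform)
    list(
      redox = if (!is.null(data$reference_ids) && length(cys_sets) > 0) {
        redox_overlap(cys_sets, data$reference_ids,
                      filtered$proteins$protein_id)
      } else {
        NULL
      },
      localization = if (!is.null(data$compartments) &&
                           nrow(classifications$cys_dependent) > 0) {
        localization_enrichment(classifications$cys_dependent,
                                data$compartments, fold_min = th$fold_min)
      } else {
        NULL
      }
    )
  })

  seq_results <- if (is.null(data$sequences)) {
    inform("No sequences available; sequence analyses skipped.")
    NULL
  } else {
    run_stage("sequence", {
      sq <- config$sequence
      cys_dep <- classifications$cys_dependent
      windows_of <- function(ids) {
        extract_cys_windows(
          data$sequences[data$sequences$protein_id %in% ids, ],
          half_width = sq$half_width
        )
      }
      isoforms <- unique(cys_dep$isoform)
      aa_enr <- purrr::map_dfr(isoforms, function(iso) {
        fg_ids <- cys_dep$protein_id[cys_dep$isoform == iso]
        ctrl_ids <- setdiff(cys_dep$protein_id, fg_ids)
        if (length(fg_ids) == 0 || length(ctrl_ids) == 0) {
          return(NULL)
        }
        aa_composition_enrichment(windows_of(fg_ids),
                                  windows_of(ctrl_ids)) |>
          mutate(isoform = iso, .before = 1)
      })
      mech_all <- bind_rows(purrr::imap(
        classifications$mechanisms,
        ~ .x$assignments
      ))
      soh_ids <- unique(mech_all$protein_id[mech_all$mechanism == "SOH"])
      ss_ids <- unique(mech_all$protein_id[mech_all$mechanism == "SS"])
      motifs_soh <- motifs_ss <- NULL
      if (length(soh_ids) > 0 && length(ss_ids) > 0) {
        w_soh <- windows_of(soh_ids)
        w_ss <- windows_of(ss_ids)
        motifs_soh <- motif_x(w_soh, w_ss, min_support = sq$min_support,
                              p_fix = sq$p_fix)
        motifs_ss <- motif_x(w_ss, w_soh, min_support = sq$min_support,
                             p_fix = sq$p_fix)
      }
      list(aa_enrichment = aa_enr, motifs_soh = motifs_soh,
           motifs_ss = motifs_ss)
    })
  }

  recovery <- if (!is.null(data$truth)) {
    run_stage("recovery", {
      truth_recovery(data$truth, classifications)
    })
  } else {
    NULL
  }

  results <- list(
    config = config,
    design = data$design,
    filtered = filtered,
    lfq = lfq,
    curves = curves,
    contrasts = contrasts,
    calibration = calibration,
    classifications = classifications,
    enrichment = enrichment,
    sequence = seq_results,
    recovery = recovery,
    truth = data$truth
  )

  if (!is.null(out_dir)) {
    run_stage("write", write_pipeline_outputs(results, out_dir))
    return(invisible(results))
  }
  results
}

#' Compare pipeline classifications against a planted truth
#'
#' @param truth Truth tibble from [generate_interactome_truth()].
#' @param classifications The `classifications` element of a pipeline run.
#' @return One-row tibble: cysteine-dependent sensitivity and empirical
#'   FDR (over (protein, isoform) pairs), planted and recovered relay (SS)
#'   percentage among mechanism-classified interactors.
#' @export
truth_recovery <- function(truth, classifications) {
  cys_dep <- classifications$cys_dependent
  true_pairs <- truth |>
    filter(.data$cys_dependent) |>
    select("protein_id", "binds_isoforms") |>
    tidyr::unnest_longer(col = "binds_isoforms") |>
    transmute(key = paste(.data$protein_id, .data$binds_isoforms))
  found_pairs <- paste(cys_dep$protein_id, cys_dep$isoform)
  tp <- sum(found_pairs %in% true_pairs$key)
  sens <- if (nrow(true_pairs) == 0) NA_real_ else tp / nrow(true_pairs)
  fdr <- if (length(found_pairs) == 0) {
    NA_real_
  } else {
    1 - tp / length(found_pairs)
  }
  mech_all <- bind_rows(purrr::map(classifications$mechanisms,
                                   ~ .x$assignments))
  truth_mech <- truth$mechanism[match(mech_all$protein_id,
                                      truth$protein_id)]
  planted_ss <- truth |>
    filter(.data$mechanism != "none") |>
    summarise(pct = 100 * mean(.data$mechanism == "SS")) |>
    pull("pct")
  recovered_ss <- if (nrow(mech_all) == 0) {
    NA_real_
  } else {
    100 * mean(mech_all$mechanism == "SS")
  }
  tibble(
    n_true_pairs = nrow(true_pairs),
    n_found_pairs = length(found_pairs),
    sensitivity = sens,
    empirical_fdr = fdr,
    planted_ss_pct = planted_ss,
    recovered_ss_pct = recovered_ss
  )
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simple <- function(x, name) {
    if (!is.null(x) && nrow(x) > 0) {
      drop_lists <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
      readr::write_tsv(drop_lists, file.path(out_dir, name),
                       progress = FALSE)
    }
  }
  simple(results$filtered$proteins, "filtered_proteins.tsv")
  simple(results$lfq, "normalized_lfq.tsv")
  simple(results$curves, "dropout_curves.tsv")
  simple(results$contrasts$wt_vs_cprs, "contrast_wt_vs_cprs.tsv")
  simple(results$contrasts$crs_vs_cprs, "contrast_crs_vs_cprs.tsv")
  simple(results$contrasts$wt_vs_crs, "contrast_wt_vs_crs.tsv")
  simple(results$contrasts$isoform_vs_rest, "contrast_isoform_vs_rest.tsv")
  simple(results$classifications$cys_dependent, "cys_dependent.tsv")
  simple(results$classifications$cp_dependent, "cp_dependent.tsv")
  simple(results$classifications$isoform_specific, "isoform_specific.tsv")
  mech <- purrr::imap_dfr(results$classifications$mechanisms, function(m, iso) {
    m$assignments |> mutate(isoform = iso, .before = 1)
  })
  simple(mech, "mechanism.tsv")
  if (!is.null(results$classifications$intersections)) {
    simple(results$classifications$intersections |>
             select(-"sets", -"proteins"),
           "intersections_cys.tsv")
  }
  simple(results$enrichment$redox, "redox_overlap.tsv")
  simple(results$enrichment$localization, "localization_enrichment.tsv")
  if (!is.null(results$sequence)) {
    simple(results$sequence$aa_enrichment, "aa_enrichment.tsv")
    simple(results$sequence$motifs_soh, "motifs_soh.tsv")
    simple(results$sequence$motifs_ss, "motifs_ss.tsv")
  }
  simple(results$recovery, "recovery.tsv")
  simple(fdr_at_threshold(results$calibration,
                          tau = c(results$calibration$tau, 0.5, 1, 2)),
         "calibration_fdr.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("prxia")),
    seed = results$config$seed,
    config_hash = rlang::hash(unclass(results$config)),
    thresholds = results$config$thresholds,
    calibration = list(
      tau = results$calibration$tau,
      alpha = results$calibration$alpha,
      n_perm = results$calibration$n_perm,
      included_fraction_real = results$calibration$included_fraction_real
    ),
    decisions = list(
      p_gate_cys = results$config$thresholds$p_mode_cys,
      p_gate_isoform = results$config$thresholds$p_mode_isoform,
      permutations_within_isoform = TRUE,
      quantile_normalization = "joint across all samples",
      unique_peptide_column = "global"
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
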