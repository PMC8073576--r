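test_that("alignment scores equal brute-force enumeration on short pairs", {
  b62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  set.seed(81)
  for (k in 1:30) {
    a <- sample(aa20, sample(2:7, 1), replace = TRUE)
    b <- sample(aa20, sample(2:7, 1), replace = TRUE)
    dp <- needleman_wunsch_align(paste(a, collapse = ""),
                                 paste(b, collapse = ""))
    expect_equal(dp$score, bf_align_score(a, b, b62), tolerance = 1e-9)
  }
})

test_that("alignment summary statistics behave on canonical inputs", {
  ident <- needleman_wunsch_align("MKVLCDEFGH", "MKVLCDEFGH")
  expect_equal(ident$identity, 100)
  expect_equal(ident$similarity, 100)
  al <- needleman_wunsch_align("HEAGAWGHEE", "PAWHEAE")
  expect_gte(al$similarity, al$identity)
  expect_true(al$similarity >= 0 && al$similarity <= 100)
  # aligned strings reproduce the score under the scoring scheme
  expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
  expect_error(needleman_wunsch_align("MKXV", "MKV"), "position 3")
  expect_error(needleman_wunsch_align("", "MKV"), "non-empty")
  expect_equal(tidy(ident)$similarity, 100)
})

test_that("the pairwise similarity matrix is symmetric with a 100 diagonal", {
  truth <- generate_interactome_truth(n_background = 4, n_interactors = 0,
                                      n_decoys = 0, seed = 82)
  seqs <- generate_protein_sequences(truth, length_range = c(40L, 60L),
                                     seed = 82)
  m <- pairwise_similarity_matrix(seqs)
  expect_equal(diag(m), setNames(rep(100, 4), seqs$protein_id))
  expect_lt(max(abs(m - t(m))), 1e-9)
  one <- needleman_wunsch_align(seqs$sequence[1], seqs$sequence[2])
  expect_equal(m[1, 2], one$similarity)
})

test_that("cysteine windows are centered, padded and inverse-consistent", {
  w <- extract_cys_windows(c(P1 = "AAAACAAAA"))
  expect_equal(w$window, "AAAACAAAA")
  expect_equal(w$position, 5)
  expect_equal(extract_cys_windows(c(P2 = "CAAAA"))$window, "----CAAAA")
  expect_equal(nrow(extract_cys_windows(c(P3 = "AAAA"))), 0)

  truth <- generate_interactome_truth(n_background = 20, n_interactors = 0,
                                      n_decoys = 0, seed = 83)
  seqs <- generate_protein_sequences(truth, seed = 83)
  w2 <- extract_cys_windows(seqs)
  expect_true(all(substr(w2$window, 5, 5) == "C"))
  expect_true(all(nchar(w2$window) == 9))
  # every reported center really is a cysteine in the source sequence
  src <- setNames(seqs$sequence, seqs$protein_id)
  expect_true(all(substr(src[w2$protein_id], w2$position, w2$position) == "C"))
})

test_that("shuffling preserves composition and converges to it", {
  # a single-residue-type sequence shuffles to itself: background windows
  # are exactly the foreground windows
  seqs <- tibble::tibble(protein_id = "P1", sequence = "CCCCCCCC")
  fg <- extract_cys_windows(seqs)
  bg <- shuffle_background(seqs, n_shuffles = 3, seed = 84)
  expect_setequal(unique(bg$window), unique(fg$window))
  expect_equal(nrow(bg), 3 * nrow(fg))

  truth <- generate_interactome_truth(n_background = 40, n_interactors = 0,
                                      n_decoys = 0, seed = 85)
  seqs2 <- generate_protein_sequences(truth, length_range = c(200L, 300L),
                                      seed = 85)
  comp <- function(x) table(factor(unlist(strsplit(x, "")), levels = aa20))
  expect_identical(shuffle_background(seqs2, n_shuffles = 2, seed = 87),
                   shuffle_background(seqs2, n_shuffles = 2, seed = 87))

  # flanking frequencies converge to overall composition for large corpora
  bg2 <- shuffle_background(seqs2, n_shuffles = 60, seed = 88)
  flanks <- paste0(substr(bg2$window, 1, 4), substr(bg2$window, 6, 9))
  flank <- table(factor(unlist(strsplit(flanks, "")), levels = aa20))
  flank_freq <- as.vector(flank / sum(flank))
  overall <- comp(seqs2$sequence)
  overall_freq <- as.vector(overall / sum(overall))
  expect_lt(max(abs(flank_freq - overall_freq)), 0.01)
})

test_that("composition enrichment is calibrated on null input", {
  set.seed(89)
  fg <- tibble::tibble(window = random_windows(1200))
  ctrl <- tibble::tibble(window = random_windows(4000))
  enr <- aa_composition_enrichment(fg, ctrl)
  expect_equal(nrow(enr), 20)
  expect_true(all(enr$q >= enr$p))
  expect_true(all(enr$q >= 0.05))
  expect_lt(max(abs(log2(enr$fold))), log2(1.25))
  expect_error(aa_composition_enrichment(fg[0, ], ctrl), "non-empty")
})

test_that("a residue absent everywhere gets fold 1 and p 1", {
  no_w <- function(n) {
    vapply(seq_len(n), function(i) {
      s <- sample(setdiff(aa20, "W"), 9, replace = TRUE)
      s[5] <- "C"
      paste(s, collapse = "")
    }, character(1))
  }
  set.seed(90)
  enr <- aa_composition_enrichment(tibble::tibble(window = no_w(300)),
                                   tibble::tibble(window = no_w(300)))
  row <- enr[enr$residue == "W", ]
  expect_equal(row$fold, 1)
  expect_equal(row$p, 1)
})

test_that("a planted two-fold residue enrichment is detected", {
  truth <- generate_interactome_truth(n_background = 0, n_interactors = 300,
                                      n_decoys = 0, isoforms = "PRDX1",
                                      multi_bind_fraction = 0, seed = 41)
  spec <- data.frame(isoform = "PRDX1", offset = c(-3, -2, 2, 3),
                     residue = "R", fraction = 0.085)
  seqs <- generate_protein_sequences(truth, motif_spec = spec, seed = 41)
  ctrl_truth <- generate_interactome_truth(n_background = 300,
                                           n_interactors = 0, n_decoys = 0,
                                           seed = 43)
  ctrl_seqs <- generate_protein_sequences(ctrl_truth, seed = 43)
  enr <- aa_composition_enrichment(extract_cys_windows(seqs),
                                   extract_cys_windows(ctrl_seqs))
  row <- enr[enr$residue == "R", ]
  expect_gte(row$fold, 1.8)
  expect_lte(row$fold, 2.2)
  expect_lt(row$q, 0.05)
})

test_that("motif discovery recovers planted patterns and stays quiet on null", {
  set.seed(7)
  fgw <- random_windows(1000)
  fgw[1:300] <- vapply(fgw[1:300], function(s) {
    s <- strsplit(s, "")[[1]]
    s[2] <- "R"
    s[7] <- "E"
    paste(s, collapse = "")
  }, character(1))
  ctw <- random_windows(5000)
  mx <- motif_x(tibble::tibble(window = fgw), tibble::tibble(window = ctw))
  expect_gte(nrow(mx), 1)
  expect_true(any(substr(mx$motif, 2, 2) == "R" &
                    substr(mx$motif, 7, 7) == "E"))
  # self-consistency: reported support equals a from-scratch recount
  for (i in seq_len(nrow(mx))) {
    pat <- strsplit(mx$motif[i], "")[[1]]
    match_all <- rep(TRUE, length(fgw))
    for (pos in which(pat != "." & seq_along(pat) != 5)) {
      match_all <- match_all & substr(fgw, pos, pos) == pat[pos]
    }
    expect_equal(sum(match_all), mx$support[i])
    expect_gte(mx$support[i], 10)
  }

  null <- motif_x(tibble::tibble(window = random_windows(500)),
                  tibble::tibble(window = random_windows(5000)))
  expect_equal(nrow(null), 0)
  tiny <- motif_x(tibble::tibble(window = random_windows(5)),
                  tibble::tibble(window = random_windows(100)))
  expect_equal(nrow(tiny), 0)
  expect_error(motif_x(tibble::tibble(window = c("AAAACAAAA", "AAC")),
                       tibble::tibble(window = "AAAACAAAA")),
               "same length")
})
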