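# Shared oracles and fixture builders, independent of the code paths they
# check.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# numerical quadrature of the marginal dropout probability
# integral of N(y; mu, sigma^2) * Phi((rho - y)/zeta) dy over a finite
# bracket wide enough to hold all the Gaussian mass
quad_missing_prob <- function(mu, sigma, rho, zeta) {
  stats::integrate(function(y) dnorm(y, mu, sigma) * pnorm((rho - y) / zeta),
                   lower = mu - 12 * sigma, upper = mu + 12 * sigma,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# brute-force global alignment score: exhaustive recursion over all
# alignments; affine gap run of length L costs open + L*ext; a gap run is an
# end gap (free) iff the other sequence is untouched or exhausted there
bf_align_score <- function(a, b, sub, open = 10, ext = 0.5) {
  n <- length(a)
  m <- length(b)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[a[i], b[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (j == 1 || j == m + 1) 0 else if (prev == "X") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (i == 1 || i == n + 1) 0 else if (prev == "Y") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "S")
}

# exhaustive exclusive-intersection counts over all 2^k - 1 membership
# patterns
bf_intersections <- function(sets) {
  k <- length(sets)
  universe <- unique(unlist(sets))
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    ids <- universe
    for (i in seq_len(k)) {
      ids <- if (inset[i]) intersect(ids, sets[[i]]) else setdiff(ids, sets[[i]])
    }
    if (length(ids) > 0) {
      out[[paste(names(sets)[inset], collapse = "&")]] <- sort(ids)
    }
  }
  out
}

# random fixed-width cysteine windows
random_windows <- function(n, width = 9) {
  vapply(seq_len(n), function(i) {
    s <- sample(aa20, width, replace = TRUE)
    s[(width + 1) / 2] <- "C"
    paste(s, collapse = "")
  }, character(1))
}

# small simulated experiment used by several files
small_null_sim <- function(n = 150, seed = 1, isoforms = "PRDX1") {
  truth <- generate_interactome_truth(
    n_background = n, n_interactors = 0, n_decoys = 0,
    low_peptide_fraction = 0, seed = seed
  )
  simulate_lfq_experiment(truth, prdx_design(isoforms = isoforms), seed = seed)
}

# apply the pre-modeling filters to a simulated experiment and return the
# filtered log2 LFQ table (the modeling stages always run downstream of the
# replication filter)
filtered_log2_lfq <- function(sim) {
  raw <- sim$lfq
  raw$intensity <- 2^raw$intensity
  attr(raw, "scale") <- "raw"
  flt <- filter_proteins(sim$proteins, raw, sim$design)
  log2_transform(flt$lfq)
}
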