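---
title: "Dropout-aware analysis of peroxiredoxin interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dropout-aware analysis of peroxiredoxin interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prxia)
```

## The problem

An immunoprecipitation–mass spectrometry (IP-MS) screen of the five 2-Cys
peroxiredoxin isoforms compares, per isoform, a wild-type bait with a
resolving-cysteine mutant (`CRS`) and a catalytic-dead double mutant
(`CPRS`), in three biological replicates. Label-free quantification
produces one intensity per protein group per sample, with a large fraction
of cells not quantified — and the missingness is informative: the
probability that a value is absent rises steeply as a protein's abundance
falls toward the detection limit. In a screen whose very hypothesis is
that many preys *disappear* with the catalytic-dead bait, discarding or
imputing missing values throws away (or fabricates) exactly the signal of
interest. `prxia` therefore treats missingness as part of the likelihood.

## The dropout model

Each sample $j$ carries a probit dropout curve: a cell with latent log2
intensity $y$ is missing with probability $\Phi((\rho_j - y)/\zeta_j)$,
where $\rho_j$ is the intensity of 50% dropout and $\zeta_j > 0$ the curve
width (both in log2 units). For protein $i$ with condition means
$\mu_{ic}$ and shared residual sd $\sigma_i$, the joint log-likelihood is

$$
\ell_i=\sum_{j\ \mathrm{obs}}\Big[\log N(y_{ij};\mu_{ic(j)},\sigma_i^2)
+\log\big(1-\Phi\big(\tfrac{\rho_j-y_{ij}}{\zeta_j}\big)\big)\Big]
+\sum_{j\ \mathrm{miss}}\log\Phi\Big(\tfrac{\rho_j-\mu_{ic(j)}}
{\sqrt{\zeta_j^2+\sigma_i^2}}\Big).
$$

The missing-cell term is the exact marginal
$\int N(y;\mu,\sigma^2)\,\Phi((\rho-y)/\zeta)\,dy$ (verified against
numerical quadrature in the test suite); the observed-value selection term
depends only on the data, so it shifts the objective without moving the
optimum. A missing cell pulls the fitted mean toward and below the
sample's detection limit — the model's replacement for imputation.

### Estimating the curves

$\rho_j$ and $\zeta_j$ are the mean and sd of sample $j$'s
*detection-limit proxy set*: intensities observed in $j$ for proteins
missing in at least one replicate of the same (isoform, genotype)
condition. When that set has fewer than 20 members (nearly complete
data), the estimator falls back to the sample's 10th percentile with
$\zeta_j = 1$ and flags the sample. The proxy estimator carries a known
upward selection tilt in $\rho$ of roughly half a curve width — only
values *above* the limit are ever observed — which the test suite pins to
an envelope of $[-0.3, +0.75]$ around the generating midpoint. Downstream
results are insensitive to this tilt: the same curves are used for the
real fit and for every label permutation, so the calibration compares
like with like.

### Optimization

Per protein, blockwise coordinate ascent: safeguarded Newton steps on each
condition mean (each mean subproblem is concave), then a golden-section
update of $\sigma$ on the log scale over $[0.05, 10]$, iterated to an
objective tolerance of $10^{-8}$ (at most 200 sweeps), vectorized across
proteins. For sparse proteins the likelihood can be bimodal — a narrow
mode hugging the observed values at small $\sigma$ and a broad
dropout-dominated mode — so the ascent runs from two systematic starts
(the replicate sd, and a start biased to the other regime) and keeps the
better optimum; the test suite checks the result dominates a dense
$200 \times 50$ grid of the identical objective.

Two conventions handle degeneracy:

- **All-missing conditions.** The unconstrained MLE of a condition with
  no observed value is $-\infty$. The reported mean is fixed at
  $\bar\rho - 2\bar\zeta$ over the condition's samples — a point where
  per-replicate dropout probability exceeds 97%, consistent with every
  replicate missing, and comfortably inside the likelihood's flat region.
- **Information for all-missing conditions.** The observed Fisher
  information evaluated at that reporting convention would be arbitrarily
  small (the likelihood is flat out there), which is not a statement
  about the data but about where we chose to report the mean. The
  curvature is therefore evaluated where the dropout curve actually
  constrains a censored mean — at the detection midpoint ($z = 0$), i.e.
  roughly one unit of information per missing cell per
  $\zeta_j^2 + \sigma_i^2$. Proteins observed high in one condition and
  entirely absent in the other are the screen's canonical hits; this
  convention lets their evidence register while pure-null data keep
  nominal error rates (both properties are asserted in the tests).

### Variance moderation and testing

With three replicates, per-protein variances are unusable raw. The ML
variances are first rescaled to residual footing
($s_i^2 = \hat\sigma_i^2 \, n_i/\mathrm{df}_i$, undoing the ML
denominator), then a scaled inverse-$\chi^2$ prior $(d_0, s_0^2)$ is
moment-matched on the well-observed proteins (residual df $\ge 3$) with
the $\chi^2$ sampling component deconvolved:
$\mathrm{Var}/\mathrm{E}^2 = (1 + 2/(d_0-4))(1 + 2/f) - 1$ solved for
$d_0$. Skipping the deconvolution, or fitting on heavily censored rows
(whose variances carry a truncation bias), underestimates $s_0^2$ by tens
of percent and makes every standard error anti-conservative. Posterior
variances $(d_0 s_0^2 + \mathrm{df}_i s_i^2)/(d_0 + \mathrm{df}_i)$ feed
the Fisher information; contrasts use a t reference with
$\mathrm{df}_i + d_0$ degrees of freedom and BH adjustment within each
contrast family.

## Permutation calibration

The WT/CPRS labels are shuffled within each isoform (the replicate
structure and the per-sample curves stay fixed — the detection limit is a
property of the sample, not its label), the model refit, and the
randomized $|\Delta|$ pooled across isoforms and permutations. The
threshold $\tau$ is the $1-\alpha$ quantile (type-7) of that pool: the
fold change at which a fraction $\alpha$ of randomized data is still
included. The empirical FDR at any $\tau'$ is the mean per-permutation
count above $\tau'$ over the real count above $\tau'$, clipped to
$[0, 1]$.

One property deserves emphasis: a $3{+}3$ label shuffle *redistributes* a
true shift, it never removes it. Each genuinely bound protein contributes
$|\Delta| \approx \{\delta/3 \cdot k\}$ values to the randomized pool in
every permutation, so with strong real effects present the estimated FDR
is an upper bound on the realized FDR, not an unbiased estimate — the
tests assert the bound and that the realized FDR at $\tau$ stays
controlled. Pooling across the five isoform comparisons before taking the
quantile (rather than per-isoform thresholds) is the default because the
published analysis reports a single cutoff.

## Classification gates

Defaults follow the screen's reporting conventions: cysteine-dependent
and peroxidatic-cysteine-dependent sets gate at log2 fold change $> 1$
with raw $p < 0.05$; isoform-specific sets (isoform vs the pooled other
isoforms, all genotypes) use BH-adjusted $q < 0.05$. Only positive fold
changes count as binding; mutant-enriched proteins are reported
separately. All four thresholds are config parameters, never hard-coded,
and the chosen gate is recorded in the run manifest.

For the mechanism partition (SOH $=$ WT $\cap$ CRS, SS $=$ WT
$\setminus$ CRS, CRS-only excluded), the pipeline judges "binds the CRS
bait" on the CRS-vs-CPRS fold-change *point estimate* alone
($\Delta > 1$): reusing the full significance gate would turn lack of
power into "does not bind", systematically inflating the relay group.
`classify_mechanism()` itself is set-agnostic, so either convention can
be composed by hand.

Compartment enrichment selects set members with $\Delta > \log_2 10$ on
the WT-vs-CPRS contrast (that contrast defines "binder"; the source
analysis names the 10-fold selection but not the contrast) and compares
their compartment distribution to the full annotation table; fractions
are over all selected proteins, so per-isoform fractions sum to one minus
the unannotated fraction.

## Sequence analyses

Isoform similarity uses a Needleman–Wunsch global alignment with affine
gaps (BLOSUM62, open 10, extend 0.5, a gap of length $L$ costing
$10 + 0.5L$) and free end gaps, the convention of the classic pairwise
tools for full-length proteins; similarity is the percentage of alignment
columns with a positive substitution score, identity the percentage of
identical columns, both over the full alignment length. Traceback ties
break deterministically (diagonal, then gap in the second sequence).

Cysteine windows are 9-mers ($\pm 4$ residues — "eight flanking amino
acids" and "9 centered on the cysteine" are the same window) padded with
`-` past the termini; pads and the center never enter any count. Each
window set is compared against either the windows of the other isoforms'
interactors (composition enrichment) or the other mechanism group
(motif discovery); shuffled backgrounds permute every sequence uniformly
(exact composition conservation) and re-extract windows. Composition
fold changes carry a 0.5 pseudocount on both counts; p-values are
two-sided binomial tests of the foreground count against the raw control
frequency, BH-adjusted over the 20 residues. Motif discovery is the
classic iterative scheme: fix the (position, residue) pair with the
smallest one-sided binomial p (ties by p, then position, then residue),
filter both sets, recurse; a pair is fixed only below $p = 10^{-4}$
(a default chosen for corpora of a few hundred to a few thousand
windows) with at least 10 supporting windows, and the control count gets
a 0.5 pseudocount so a filtered-to-empty background cannot trigger
runaway fixing. Completed motifs remove their foreground windows and the
search restarts against the full control.

## The synthetic-data generator

The generator emulates what the analysis assumes: log2-normal baselines
(mean 25, sd 3 — a typical LFQ dynamic range), additive planted binding
effects (default 4 log2 units, the regime of a strong bait–prey
enrichment), Gaussian replicate noise (default sd 0.5), and probit
dropout with the midpoint solved so realized missingness hits a target
(default 34%). Effect placement encodes the biology: SOH-mechanism
interactors are enriched with WT and CRS baits, SS-mechanism with WT
only, non-cysteine-dependent binders with every genotype of their
isoform. Decoy rows (`REV__`/`CON__`), sub-threshold peptide counts,
redox-sensitivity flags (80% of binders, 13% of background — the regime
the published screen reports), compartment biases and cysteine-flanking
residue plants exercise the filters and the annotation/sequence stages.
Each generator op draws from its own RNG stream derived from one seed
(spaced by a large prime so nearby user seeds never share a stream).

What it does *not* emulate — and hence what green tests do not show about
real data: peptide-to-protein rollup and shared-peptide ambiguity,
sample-level batch effects or varying IP efficiency (the quantile
normalization step is exercised, but the generator gives it little to
correct), intensity-dependent variance, correlated preys (complexes), or
any structure in which cysteine actually carries an interaction.

## Problem sizes

The test suite and the acceptance script run the statistical checks at
sizes chosen to make the assertions sharp but quick: 1000 background
proteins for null calibration, 500 null + 100 planted ($\Delta = 4$) for
sensitivity/FDR, 150 interactors across five isoforms for the mechanism
mix, 15–100 label permutations, 100 random short pairs for the alignment
oracle, and $10^3$–$5 \times 10^3$ windows for sequence recovery. The
defaults baked into `pipeline_config()` (100 permutations, 100 shuffles)
match the published workflow.

## Known limitations

- The dropout curve is shared across proteins within a sample; real
  detection limits vary with peptide properties.
- The proxy-set estimator of $\rho_j$ is deliberately simple and carries
  the documented upward tilt; a likelihood-based curve fit would remove
  it at the cost of a considerably heavier estimation step.
- The permutation FDR is conservative in the presence of strong true
  effects (see above).
- Mechanism assignment inherits the power of the CRS-vs-CPRS contrast;
  at three replicates a residual few-percent leakage between the SOH and
  SS groups remains.
- All-missing-condition fold changes are bounded by the reporting
  convention, so extreme enrichments of low-abundance preys are
  understated (a property of any censored measurement, made explicit
  here).
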