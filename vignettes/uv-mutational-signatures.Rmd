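---
title: "Models and methods behind uvsig"
author: "uvsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uvsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(uvsig)
```

This vignette explains the statistical models, the numerical choices and
the design decisions inside `uvsig`, and states what the synthetic-data
generator does and does not emulate. The package analyzes somatic
mutation data from UV-exposed melanoma models downstream of variant
calling: consensus filtering, mutation spectra, signature extraction,
catalog comparison, copy-number burden, cohort statistics and UV
dosimetry.

## From call sets to mutation events

Somatic calls from multiple callers are intersected per
(sample, chromosome, position, ref, alt); known polymorphisms are then
removed by site (chromosome, position, ref, alt), the keying convention
of dbSNP/Ensembl-variation exports. Intersection trades sensitivity for
precision, the standard choice when orthogonal callers are available.

UVB photochemistry produces lesions at adjacent pyrimidines, so two
substituted neighboring bases (the classic CC>TT) are one mutational
event. `collapseDinucleotideEvents()` merges SNV pairs at adjacent
positions within a sample; runs of three or more merge greedily left to
right into pairs, since longer joint substitutions are not part of the
model. Collapsing is idempotent. Dinucleotide events count once toward
total burden, are reported on their own axis, and are excluded from the
SBS96 catalog and the six-class tallies — the catalog describes
single-base substitution processes.

Classification is pyrimidine-centric: a purine-reference SNV is
re-expressed on the reverse complement, so G>A in 5'-AGA-3' is C>T in
context TCT. A C>T is "at CpG" iff the 3' neighbor on the
pyrimidine-bearing strand is G (context `.CG`); elevated deamination and
dimer rates at methylated CpG make this sub-tally diagnostically
useful. Events whose flanks contain an ambiguous base are flagged and
excluded from context analyses rather than guessed.

Burden is `events * 1e6 / capture_size_bp`. The capture footprint is a
required user parameter: it is a property of the exome design, not of
the call set, and no default could be correct.

## Spectra and strand bias

The SBS96 catalog is a samples x 96 count matrix in the fixed COSMIC
channel order (classes C>A, C>G, C>T, T>A, T>C, T>G; 16 flanking
contexts alphabetical within class), so catalogs, signature files and
external references interoperate without reindexing — any channel-order
mismatch is an error, never silently reordered.

Spectra can be normalized to the trinucleotide composition of the
captured territory: each channel's count is divided by the occurrences
of its context in the region set (both strands via complementation) and
scaled per million. Whether to use the capture regions or a whole exome
is left to the caller via the region set argument; the choice changes
rates, never counts.

Transcriptional strand is assigned from where the pyrimidine of the
mutated pair sits relative to an overlapping gene: on the template
(transcribed) strand or the coding (untranscribed) strand. Intergenic
events and events under genes annotated on both strands are `unknown`
and excluded from strand tallies; with no strand-resolved evidence, any
label would be arbitrary.

The strand-bias test conditions on the total count: under the null a
mutation falls on either strand with probability 1/2, so the
transcribed count is Binomial(n, 1/2) — the conditional form of the
classical two-count Poisson rate test. We use the minimum-likelihood
two-sided rule (`stats::binom.test`), which gives 112/1024 for the
(8, 2) case. Being exact, the test is conservative at small n: at
n = 100 its achievable size nearest below 0.05 is 0.0352, so null
rejection rates sit visibly under the nominal level. That is a property
of discreteness, not an implementation artifact. Log2 strand ratios use
a +0.5 continuity adjustment to both counts only when a count is zero;
raw counts are always reported. Tests aggregate over an experimental
group by default, since per-tumor strand counts are small.

## Signature extraction

The catalog (as channels x samples `V`) is factorized as `V ≈ W H`,
`W >= 0` column-stochastic, `H >= 0`, by multiplicative updates under
the generalized Kullback-Leibler divergence (the natural objective for
count data; Frobenius is available for cross-objective robustness
checks). The objective is non-increasing along the update trace and a
relative-change tolerance stops iteration.

**Initialization.** The default is NNDSVD (non-negative double SVD),
which is deterministic and starts at an extremal vertex of the
factorization's solution set. This matters: when one process is flat
(mass in every channel), the non-negative factorization is not unique —
uniform mass can be shifted between factors without changing the fit —
and random dense initializations converge to interior points of that
ambiguity where the flat factor absorbs part of the peaked one. The
extremal start recovers the flat factor essentially up to sampling
noise. Random initialization remains available and is used in tests of
update monotonicity.

**Rank selection.** For each candidate rank, every sample's counts are
resampled by a multinomial bootstrap, each replicate is factorized, the
pooled replicate profiles are partitioned into rank clusters by
k-medoids on cosine distance (`cluster::pam`, deterministic given the
distance matrix, so no restarts are needed), and stability is the mean
silhouette width — at rank 1, where a silhouette is undefined, the mean
cosine to the medoid. Two facts shape the selection rule. First, the
absolute reconstruction error of a count catalog sits on the Poisson
noise floor (about the square root of the total mutation count), so
error differences between ranks are noise-scale and a rule keyed to the
error trend either keeps the trivially stable rank 1 or chases noise at
high ranks. Second, profile stability alone can over-select: a single
peaked process can be split into reproducible sub-profiles, but then
which cluster a sample loads on is arbitrary across replicates, which
the cophenetic coefficient of the sample-consensus matrix detects (it
collapses to ~0.6 on rank-1 catalogs while staying above 0.95 at a true
rank). The selected rank is therefore the largest candidate with
stability >= 0.8 and sample-consensus cophenetic >= 0.9 (both
thresholds exposed); if none qualifies, the maximally stable rank.
Error, cophenetic, explained variance, RSS, dispersion and Hoyer
sparseness are all reported per rank for inspection.

**Consensus and polish.** Consensus profiles are normalized cluster
centroids, refit on the unresampled catalog by a warm-started
factorization so the reported signatures are a stationary point of the
objective on the observed data. Exposures for the report are NNLS
refits on the consensus profiles.

**Activities.** Per sample, the count vector is regressed on the
signature profiles by non-negative least squares
(`pracma::lsqnonneg`). The fitted intensities give each channel a
posterior distribution over signatures; a channel's mutations are
allocated proportionally to that posterior when its maximum is at least
0.5, and fall into the per-sample `unassigned` pool otherwise, so
activities plus unassigned reconstruct the total exactly. The 0.5
posterior threshold is this package's operationalization of an
"unassigned fraction" — published extractors report such fractions
without a common rule — and with exactly two signatures the maximum
posterior can drop below 0.5 only at ties, so the pool is nearly empty
at K = 2; it becomes meaningful at larger K or lower thresholds.

## Catalog comparison

Cosine similarity is computed on raw non-negative profiles
(scale-invariant). Empirical p-values permute the entries of the
*second* profile (which of the two is permuted is a flag; the default
shuffles the reference) and use the `(1 + hits) / (n + 1)` estimator so
p is never zero. For vectors short enough that all permutations can be
enumerated (length! <= 5040), the exact tail fraction over all
permutations is returned instead. The default 1e6 draws matches the
convention for signature-catalog comparisons. Cross-extractor
agreement (e.g., KL vs Frobenius objectives, different resampling) is
summarized as a signed Pearson correlation matrix, where discordance
appears as negative values after mean-centering.

## Copy-number burden

Segments pass if |log2 ratio| >= 0.2 with support from at least five
bins; the threshold comparison is inclusive, so boundary segments are
reported. The altered-genome fraction is the altered footprint divided
by the total segmented footprint, which makes it invariant to splitting
segments and confined to [0, 1]. Sex chromosomes are included by
default with a flag to drop them. Overlapping segments within a sample
are a validation error, not silently merged.

## Cohort statistics

"Nonparametric ANOVA" is implemented as Kruskal-Wallis followed by
pairwise Mann-Whitney with Benjamini-Hochberg adjustment — the standard
reading of that phrase. Mann-Whitney p-values are exact for combined
n <= 20 without ties and use the tie-corrected normal approximation
otherwise. Tukey HSD uses the studentized range via `TukeyHSD`; Fisher
LSD computes unadjusted pairwise t statistics on the pooled residual
variance and is only protected by a significant omnibus F. Survival
curves are product-limit estimates (`survival::survfit`). The
Gehan-Breslow-Wilcoxon statistic is built directly — at each event time
the observed-minus-expected difference is weighted by the total number
at risk, squared over the summed hypergeometric variances — because the
rho-family in `survival::survdiff` weights by the Peto-Peto survival
estimate, not by the number at risk. Group comparisons default to
versus-control with an all-pairs flag.

## Dosimetry

The erythemal action spectrum is 1 up to 298 nm, `10^(0.094(298 - l))`
to 328 nm and `10^(0.015(C - l))` to 400 nm. The default `C = 140`
makes the third segment continuous at 328 nm; `C = 139` selects the
original 1987 coefficients, whose jump at 328 nm is below 1e-3.
Erythemally effective energy weights an unweighted dose by
`trapz(w * S) / trapz(S)` on the spectrum's native grid: a two-point
spectrum then reduces to the hand-checkable two-point quadrature
`(w(l1) S1 + w(l2) S2) / (S1 + S2)`, which is the right semantics for
line-like lamp spectra. Linear resampling before weighting (for coarse
continuum tabulations, where the weight varies strongly within a grid
step) is available explicitly via `resample_nm` rather than triggered
implicitly, because interpolation does not commute with the strongly
nonlinear weight and would silently change line-spectrum results. One
SED is 10 mJ/cm² of erythemally weighted UV; the tanning-session
helper chains SED -> mJ/cm², the UVB-attributable split and the ratio
to a reference lamp's effective energy.

## The synthetic-data generator

The generator exists so that `simulate -> analyze` recovers planted
parameters; its defaults encode the study-scale regime the package
targets.

- **Reference and genes**: i.i.d. bases at a requested GC fraction
  (default 0.45, a mouse-like value), non-overlapping genes with
  alternating strands covering ~60% of the sequence, capture = whole
  sequence. Desk-scale references (50-100 kb) already contain hundreds
  of occurrences of every trinucleotide, which is what placement needs.
- **Signatures**: `uvb_like` concentrates >90% of its mass on C>T
  channels, strongest at 5'-pyrimidine contexts in the order
  TCT > TCC > TCA > TCG — the CPD fingerprint; the background is flat.
  A profile with a substantial uniform floor would *contain* the flat
  signature and make the mixture non-identifiable for any extractor,
  so the UVB profile is deliberately concentrated, as real UVB
  signatures are.
- **Activities**: per sample and signature, a gamma-distributed level
  (CV 0.7) around the cohort mean, then a Poisson count. The
  dispersion reflects the strong tumor-to-tumor variation real cohorts
  show; with identical expected mixing in every sample the catalog
  would be rank 1 regardless of cohort size and no extractor could
  separate the processes.
- **Placement**: each mutation lands uniformly on a reference site
  matching its context (collisions re-drawn); genic C>T events are
  placed on untranscribed-pyrimidine sites with configurable odds
  rho:1, planting transcription-coupled-repair-like asymmetry. A
  configurable fraction of C>T events whose pyrimidine-strand 3'
  neighbor is C is emitted as a CC>TT pair.
- **Call sets**: three synthetic callers, each missing each true
  variant independently with a dropout probability and adding private
  false positives, to exercise the consensus logic.
- **Clinical**: exponential survival with right-censoring at a fixed
  horizon; copy-number segments tiled so the altered fraction is known
  by construction.

What the generator does *not* emulate: sequencing noise and coverage
(calls are taken as given), indel processes, regional mutation-rate
covariates (replication timing, chromatin), subclonality, and
inter-signature correlation. Passing recovery tests therefore
demonstrates the correctness of the analysis machinery under the stated
generative model, not robustness to every artifact of real exomes.

## Numerical choices and problem sizes

Multiplicative updates use a machine-epsilon floor in denominators;
convergence is relative objective change (default 1e-7, 2000
iterations inside the rank survey). The recovery analyses run at 30
samples with expected 300/100 mutations per sample, ranks 1-5 and 50
bootstrap replicates — a few minutes of CPU — and the test suite uses
smaller cohorts for unit-level checks. At the 300/100 design the flat
signature's recovered cosine to truth is limited by finite-sample
likelihood flatness and typically lands between 0.92 and 0.97 across
realizations; the UVB profile recovers at 0.999 essentially always.
Tie-breaks: k-medoids uses `pam`'s deterministic build/swap; channel
order is frozen; all stochastic steps flow from a single seed through
derived stage seeds, and RNG state is restored after seeded sections so
library calls do not perturb caller RNG.

## Known limitations

- The unassigned-mutation rule is a stand-in (see above); comparisons
  with published "uncategorized" fractions should treat it as one
  operationalization among several.
- The exact strand-bias test is conservative at small counts; users
  wanting nominal-size behavior at small n should aggregate further.
- Erythemal weighting assumes relative spectra on [250, 400] nm; lamp
  spectra must be digitized by the user (figures in lamp datasheets are
  not machine-readable).
- `extractWithStability` is quadratic in `n_bootstrap * rank` at the
  clustering step; surveys far beyond rank ~10 with hundreds of
  bootstraps will be slow in pure R.
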