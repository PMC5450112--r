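---
title: "Methods: paired-array lincRNA discovery and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-array lincRNA discovery and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincdiscover)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. No empirical claim is made here that the test
suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

A two-colour genotyping array reports, per SNP marker and hybridized
sample, two fluorescence intensities X and Y — one per allele. Two assays
are run per biological sample: genomic DNA (gDNA), whose X/Y balance
reflects the germline genotype, and double-stranded cDNA, whose total
intensity reflects transcript abundance at the marker position. The
quantification rule is genotype-aware because only informative channels
carry signal:

* heterozygous (AB) markers express both alleles, so total expression is
  the channel sum `e = X + Y`;
* homozygous markers express one allele, so `e = X` for AA and `e = Y`
  for BB — the silent channel holds only background and is discarded;
* markers without a genotype call contribute missing cells.

Genotypes are called from the gDNA allele contrast θ = X/(X+Y) with fixed
thresholds: AA at θ ≥ 0.75, BB at θ ≤ 0.25, AB in the central band
0.35–0.65, and NoCall in the gaps or when X+Y falls below an intensity
floor (default: 5% of the grand median, so calls are invariant to uniform
rescaling of both channels). A θ-threshold caller was chosen over
reproducing a vendor clustering algorithm, which is proprietary and
unpublished; the thresholds are exposed as arguments. On synthetic data at
the default noise level this caller agrees with the simulated truth on
more than 99% of calls with a NoCall rate well under 2% (computed in the
acceptance suite).

Technical replicates are averaged on the raw intensity scale before
calling and quantification: replicates share their biology, so averaging
reduces measurement noise without inflating the number of biological
samples. A subject whose call rate falls below 0.95 fails QC and its
tumor/normal pair is excluded whole, since a paired analysis cannot use an
orphan member.

Normalization is per-array median scaling to the grand median followed by
`log2(e + 1)`; a pass-through mode (`scale = FALSE`) is provided because
upstream pipelines differ in whether intensities arrive already
normalized. An array with median 0 is an error rather than a silent
division by zero.

## The moderated paired t-test

With only a handful of pairs, per-marker variance estimates are unstable;
the classical remedy is empirical-Bayes moderation. For marker *g* with
*n* complete pairs, let d_i be the per-pair log2 differences, log2FC their
mean and s² their sample variance (df = n − 1; a pair missing either
member is dropped for that marker only, which maximizes the use of a
five-pair cohort). The variance model is a scaled F: s² ~ s₀²·F(df, d₀).
On the log scale this gives closed-form moment equations —
E[log s²] and Var[log s²] are digamma/trigamma expressions in (df, d₀,
s₀²) — which are solved by moment matching with a Newton inversion of the
trigamma function. When the observed dispersion of log s² is no larger
than sampling noise alone implies, the fit returns d₀ = ∞ with the
geometric-mean-based s₀², and the reference distribution becomes normal.
The moderated statistic is

t = log2FC / sqrt(s̃²/n), with s̃² = (d₀·s₀² + df·s²)/(d₀ + df),

referred to Student-t with d₀ + df degrees of freedom. Two limits anchor
the implementation and are asserted in tests: d₀ = 0 reproduces the
ordinary paired t-test exactly, and d₀ = ∞ uses s₀² with a normal
reference. Multiple testing is controlled with a Benjamini–Hochberg
step-up implemented directly (stable sort, enforced monotonicity, capped
at 1) and verified against an independent step-up transcription and
`p.adjust`.

The candidate filter keeps markers with p < 0.005, FDR < 0.15 and
|log2FC| > 1 — all strict, so boundary values are rejected. Candidates
are aggregated to loci by interval containment: marker maps use 1-based
positions (dbSNP convention), locus annotations are 0-based half-open
(BED), and all interval logic is half-open. Filtering is performed at the
marker level with the locus roll-up kept descriptive, and loci whose
passing markers disagree in sign are flagged discordant and excluded from
the headline up/down tallies, since a single direction per locus is what a
discovery list reports. A marker contained in more than one locus is an
ambiguity error rather than a silent double count.

## ISH scoring and rank tests

RNAscope staining is scored 0/1/2: 0 below 0.1 dots/cell (fewer than one
dot per ten cells), 2 when dots exceed 10 per cell *and* more than 10% of
dots form clusters, 1 otherwise. Two rubric gaps required decisions:
"few dot clusters" is quantified as cluster fraction ≤ 0.10 to make the
rubric computable, and a specimen with many dots but sparse clustering —
which satisfies neither the score-1 nor score-2 text exactly — is
assigned 1, because score 2 demands both of its stated conditions. Scores
from two observers are combined conservatively: ties stand, one-level
disagreements take the lower score, two-level disagreements are flagged
for adjudication and excluded. Specimens whose positive control (POLR2)
scores 0 are excluded as RNA-degraded, as are negative-control (dapB)
failures.

Group comparisons use rank tests implemented in-package with mid-ranks
for ties. The rank-sum and signed-rank tests switch to exhaustive
enumeration of the permutation null (all group assignments, or all 2ⁿ
sign flips) when the sample is small — at most 12 observations — and
otherwise use tie-corrected normal approximations with a 0.5 continuity
correction. Zero differences are dropped before signed ranking (classical
Wilcoxon); Pratt's method is available behind a flag. The two-sided
p-value is defined by |statistic − null mean| ≥ |observed − null mean|,
which makes exact and approximate branches agree closely (within 0.02 at
n = 12 on random inputs, asserted as a property test).

## Survival and stage association

Survival time is days-to-death for the dead and days-to-last-follow-up
(censored) for the alive — exactly that mapping and nothing else.
Records with zero follow-up or unavailable pathologic stage are excluded
with a per-reason report. Expression is categorized on the measurement
scale rather than by percentiles because RPKM-like values are strongly
right-skewed: initial bins ≤1, >1–5, >5–10, >10 (the printed upper bound
of the last bin merely reflects an observed maximum and is treated as
open-ended), collapsed to the binary low (≤ 1, boundary inclusive) vs
high (> 1) covariate that the survival models use.

The Kaplan–Meier estimator handles ties with events first (subjects
censored at t remain at risk for events at t). The log-rank test sums
observed-minus-expected event counts with hypergeometric variances. The
Cox model maximizes the Breslow partial likelihood by Newton–Raphson
(convergence at max |score| < 1e-8 or 50 iterations, with step-halving;
separation is reported as a diagnostic error rather than a huge
coefficient). Breslow ties were chosen over Efron as the simplest
published partial likelihood at this scale, with the choice surfaced in
the object's `ties` field. Age adjustment is done by including age as a
Cox covariate — "adjusted for age" admits a stratified-log-rank reading,
but the regression formulation is the standard one and exposes the
adjusted hazard ratio directly. The score test at β = 0 is reported
because, on tie-free data with a single binary covariate, it equals the
log-rank chi-square — an identity the tests verify numerically to 1e-6.
Stage tables collapse sub-labels onto main levels (IA/IB → I, T1a–c → T1)
and report median and quartiles with the type-7 linear-interpolation
convention (the convention used by published tables of this kind is
unknowable from the table alone, so one was fixed and documented).
Kruskal–Wallis (tie-corrected, exact permutation at total n ≤ 10) and
Fisher's exact test (full hypergeometric enumeration; sample odds ratio)
complete the association toolkit.

## Knockdown concordance

Two treatments' per-gene statistics against a common control are consumed
as given (the upstream expression pipeline that produces them is out of
scope). Genes pass at p < 0.001 (strict); concordance is summarized by
the overlap count and per-set percentages, and by the Spearman
correlation of the overlapping genes' log2 fold changes. Both ρ and ρ²
are reported: concordance write-ups sometimes print an "R²" for a
Spearman analysis, and surfacing both avoids the ambiguity.

## What the synthetic generator emulates — and what it does not

The generator plants known truth at every stage: Hardy–Weinberg genotypes
shared within a pair (MAF uniform on 0.05–0.5), genotype-clustered gDNA
intensities, cDNA totals proportional to a log-normal locus expression
level split across channels by allele balance (fixed 0.5/0.5 for AB —
allelic imbalance is deliberately not modelled), multiplicative
log-normal channel noise with CV 0.15 by default (array intensities are
positive and right-skewed; the true noise magnitude of the real platform
is unpublished, so the default is an explicit placeholder surfaced in the
configuration), planted ±2 log2-fold effects, and two pairs driven below
the call-rate floor to exercise QC. The default cohort is 7 pairs with 2
technical replicates on both assays — 32 arrays — of which 5 pairs
survive QC. Batch and plate effects, copy-number alterations,
normalization chemistry and allele-specific expression are not modelled;
a pipeline that passes these tests is validated for its arithmetic and
its statistical calibration, not for robustness to those artefacts.

The ISH generator draws dots-per-cell from a gamma distribution with the
tumor mean shifted upward, clustering increasing with dot density, and a
planted fraction of degraded specimens; its default shape lands the
post-QC cohort near 88 tumors and 31 normals. The survival generator
draws log-normal expression (σ = 1.5) calibrated so a target fraction
exceeds the cutpoint 1.0, uniform ages 35–80 (spanning breast-cancer
diagnosis ages; the exact range is immaterial to correctness),
exponential event times under proportional hazards, and exponential
censoring tuned to an exact per-record censoring probability. Stage
labels carry a mild planted expression shift so stage-association tests
have something to find.

## Problem sizes and numerical conventions

The test suite and acceptance script choose sizes that keep every check
sharp but cheap: oracle equivalences run at n ≤ 12 where enumeration is
exact; prior recovery uses 50,000 simulated variances; Cox recovery uses
100 cohorts of n = 700; filter calibration and sensitivity use 100
five-pair cohorts of 120 markers / 20 loci each. Determinism is
end-to-end: identical seed and configuration produce byte-identical files.
Degenerate inputs are defined rather than left to chance: all-zero
differences give p = 1 with a warning, a moderated variance of exactly 0
gives p = 0 with a warning, an all-equal Kruskal–Wallis sample has H = 0,
and an array median of 0, separation in the Cox fit, or a marker mapping
to overlapping loci raise informative errors.

## Known limitations

The moderated test assumes a common variance model across markers and
independent pairs; the caller assumes two well-separated homozygote
clusters; the Cox fit assumes proportional hazards and offers no
diagnostics; pathway overlap is plain set arithmetic, not enrichment. The
locus roll-up is descriptive — FDR control is at the marker level.
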