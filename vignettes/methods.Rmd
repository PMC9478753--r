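---
title: "Replication timing and genome architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication timing and genome architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtarchitect)
```

# Scope

`rtarchitect` links DNA replication timing (RT) dynamics across cell
differentiation to 3D genome architecture. It consumes binned data —
Repli-seq S-phase fraction read counts, Hi-C intra-chromosomal contact
matrices, coverage tracks and interval annotations — and produces RT
profiles, four-way RT dynamics categories, A/B compartment calls, a
per-bin compartmentalization-degree statistic, hierarchical domain
(TAD/subTAD) trees, binned genomic features and rank-sum category
comparisons. A coupled synthetic generator plants a known architecture so
every stage can be scored against ground truth.

# The bin grid

Everything is indexed on a fixed partition of each chromosome into
100-kb bins (0-based, half-open; `build_genome()`), the resolution at
which replication domains (400–800 kb) are comfortably resolved.
Chromosomes named chrY and chrM are excluded, as is conventional for
RT analysis. A 50-kb analysis is a configuration choice
(`bin_size = 5e4`), not a separate code path.

# Replication timing

Repli-seq fractionates S phase into four windows S1–S4. The two early
and the two late fractions are highly concordant (`phase_similarity()`
quantifies this with Spearman correlations and a mutual-nearest-pair
report), so they are pooled and scored per bin as

$$\mathrm{RT} = \log_2 \frac{S_1 + S_2 + c}{S_3 + S_4 + c},$$

positive for early-replicating bins, negative for late. The pseudocount
`c` defaults to 1: it leaves the sign of every informative bin unchanged
while avoiding infinities at zero-coverage bins; bins with zero counts in
both pools are treated as missing rather than zero. At `c = 0` the score
is exactly scale-invariant (multiplying all four fractions by any
constant leaves it unchanged) and antisymmetric under early/late
exchange; both properties are enforced in the test suite.

Profiles from multiple cell types are made comparable by quantile
normalization over shared non-missing bins (via limma), which preserves
each profile's rank order. Smoothing is a running mean with an odd span
(default 3 bins): the minimal, exactly testable choice; missing bins are
excluded from windows rather than propagated.

## Replication domains

Domains are segmented by recursive binary segmentation in the spirit of
circular binary segmentation: each candidate split is the maximizer of
the two-sample t statistic along the profile, accepted when its
within-segment permutation p-value falls below `alpha` (default 0.01,
1000 permutations, fixed seed). Segments shorter than `min_seg`
(default 3 bins) are merged into the neighbour with the closer mean, and
each segment is called early or late by the sign of its mean RT. A
numerical guard treats mean differences at floating-rounding scale
(relative 1e-6) as zero and zero-residual splits as perfect steps, so
constant profiles are never split and noiseless steps are always split.
At a jump-to-noise ratio of 2 the argmax-t location estimator is the
maximum-likelihood changepoint; its localization accuracy (about 95%
of replicates within ±2 bins at 200 bins) is an intrinsic property of
the estimator at that noise level, not of the implementation.

## RT dynamics categories

With one reference (stem) profile and several differentiated profiles,
each bin is labelled by its sign pattern: `CE` (positive everywhere),
`CL` (negative everywhere), `EtoL` (positive in the reference, negative
in every differentiated type), `LtoE` (the converse), `other` for any
remaining pattern or missing value. Classification uses strict signs by
default; an optional dead zone `epsilon` sends bins with any
`|RT| < epsilon` to `other` for users who want to exclude weak calls.
Classification operates on normalized, unsmoothed profiles: smoothing
across category boundaries can flip the sign of one-bin segments, while
the per-bin sign pattern needs no noise averaging at typical depths.

# A/B compartments

Per chromosome, the contact matrix is distance-normalized (each entry
divided by the mean of its diagonal, `oe_transform()`; every unmasked
diagonal of the result has mean 1 by construction), rows of the O/E
matrix are correlated (Pearson), and the eigenvector of the largest
algebraic eigenvalue of that correlation matrix is extracted. Bins with
zero marginal contacts are masked first because constant rows break the
correlation. The eigenvector's sign is arbitrary, so it is oriented
against an external reference that is higher in active chromatin (gene
density or expression): if the Spearman correlation with the reference
is negative every value is negated; `|rho| < 0.1` flags the orientation
as uncertain and leaves the sign unchanged with a warning. Positive bins
are A, negative B; exact zeros remain unlabelled because a sign-based
definition says nothing about them.

The classical analysis calls compartments at 500 kb and refines at
100 kb. `compartments_at_resolution()` runs the pipeline at both
resolutions and aligns the fine profile to the coarse one by majority
vote over nested bins, flipping a chromosome (and flagging the flip)
when most fine calls disagree with their coarse parents. The majority
vote is this package's declared reconciliation rule; the original
description does not specify one.

## Degree of compartmentalization

For an unmasked bin $i$ with label $L$, let *same* be the sum of its
contacts to other bins labelled $L$ (the bin's own diagonal entry is
excluded as technical self-ligation signal) and *opp* the sum to bins
with the other label; the degree is
$\log_2((\mathrm{same} + c)/(\mathrm{opp} + c))$ with pseudocount
default 1 and base 2 chosen to match the RT formula. A value of 0 means
the bin interacts equally with both compartments. Note a symmetry worth
stating precisely: exchanging every A and B label globally leaves every
score unchanged (each bin's partner partition is unchanged); only
flipping a single bin's own label negates that bin's score.

# Hierarchical domains

TAD calling here is a multiscale insulation method, a deliberately
simple, fully specified stand-in for dedicated hierarchical-TAD callers
whose optimization is out of scope. The insulation of bin $i$ at window
$w$ is the mean contact count in the $w \times w$ square upstream by
downstream of $i$, log2-normalized by the chromosome mean; low values
mark boundaries. The coarsest window (default 20 bins) defines level-0
domains from local insulation minima at or below the
`boundary_quantile` (default 0.1) of the track; each finer window
(defaults 10 then 5) subdivides existing leaves one level deeper,
keeping subdivisions producing at least two children of at least 3 bins.
Within a parent, candidate minima are judged against the insulation
distribution of the parent's interior (its own edge bins are already
low), which keeps the threshold meaningful inside structured regions.
Plateaus of exactly equal low values — which arise in noiseless
constructions and structure-free gaps — contribute their edges as
boundaries; a single-bin minimum needs both neighbours strictly higher.
Level 0 is the outermost, parentless layer and the level number grows
with nesting depth. `validate_tad_tree()` checks the structural
invariants (disjoint-or-nested, child within parent, child level =
parent level + 1) on any tree.

`summarize_tad_rt()` reports domain size, level, mean RT and the
majority RT category per domain (ties are "mixed"), plus size-by-category
and RT-by-level summaries. The package reports both tables and does not
hard-code a direction for the size–level–RT relationship.

# Binned genomic features

Gene and repeat densities count midpoints (each feature contributes to
exactly one bin, making "features per bin" unambiguous); coverage mode
splits bp exactly at bin boundaries and conserves genome-wide totals. GC
content excludes ambiguous bases from the denominator. Coverage tracks
are summed as value × overlap bp per bin. Input (control) subtraction
scales the input to the ChIP total before the per-bin difference and
keeps negative values so rank-based comparisons are unaffected.
Open-chromatin restriction either clips a raw track to DHS peaks before
binning or multiplies a binned signal by the per-bin open fraction; the
mode is recorded. Annotation composition resolves overlapping bp with
the precedence promoter > exon > intron > intergenic (promoter = TSS ±
1 kb by default; the original figure does not define its categories, so
these are this package's documented choices). TSS-anchored
meta-profiles average signal in step-sized offset windows with
minus-strand anchors reversed so upstream is always left.

# Statistics

All category comparisons are two-sided Wilcoxon rank-sum tests. The
exact null distribution is used when both groups have at most 10 values
and no ties; otherwise the normal approximation with midranks,
tie-corrected variance and continuity correction. The method used is
recorded per test, since at typical bin counts only the approximation is
ever exercised. Raw p-values are reported with the significance bands
`*` p < 1e-3, `**` p < 1e-5, `***` p < 1e-10; no multiple-testing
correction is applied by default (a Benjamini–Hochberg option exists)
to match the original presentation of raw starred p-values.

# The synthetic generator

`plant_truth()` draws contiguous category segments with geometric
lengths (mean 5 bins = 500 kb, matching the replication-domain scale; a
scale was reported for real data, not a distribution, so geometric is
this package's minimal choice). RT states follow the category
definitions across one reference and N−1 differentiated types (default
N = 5, mirroring a stem line plus four lineages); `other` bins get
independent random states. Compartment truth is tied to RT state (A =
early, B = late); the `discordant` option plants reference-cell EtoL
bins in B and LtoE bins in A to reproduce the discordance scenario in
which switching regions already sit in the compartment of their future
RT state. Domain truth nests two children inside ~10-bin parents over
early runs and lays ~20-bin flat parents over late runs.

Counts are negative binomial (dispersion 0.02 by default; 0 gives
Poisson) at 100 reads per bin per fraction, with the early/late balance
set so the expected RT magnitude is 1 log2 unit — values a Repli-seq
practitioner would call a realistic, well-powered experiment. Contacts
are Poisson around a power-law decay (exponent −1) times a plaid boost
for same-compartment pairs and a per-shared-level domain boost. Mark
signals are truncated Gaussians whose mean shifts by `mark_effect` on
the preferred state (active/accessibility: early; repressive: late).
All generators derive independent sub-streams from one root seed and are
bit-reproducible.

What the generator does *not* emulate: mappability and copy-number
artifacts, inter-chromosomal contacts, matrix balancing biases,
lineage-specific (non-consistent) RT switching, and realistic
segment-length or contact-decay heterogeneity. Passing recovery tests
therefore demonstrates correctness of the inference machinery under the
stated statistical model, not performance on real ENCODE-scale data.

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
chromosomes of 100–2000 bins, 20–100 simulation replicates, 1000
permutations or null simulations per test — sizes at which every
distributional claim in the suite is stable under the fixed seeds while
the whole suite completes in minutes. `run_all()` writes a manifest
with md5 checksums of every output, so a re-run under the same
configuration and seed is verifiably identical.

# Known limitations

- The segmentation and TAD callers are stand-ins that preserve the
  published semantics (CBS-style changepoints; level-0 = outermost
  domains) but not the exact algorithms of DNAcopy or HiTAD.
- Compartment orientation accepts a single reference track; combining
  gene density with expression is left to the caller.
- No ICE/KR balancing, loop calling, trans contacts or saddle analysis.
- Boundary localization at low signal-to-noise is limited by the
  maximum-likelihood estimator itself (see the segmentation section).
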