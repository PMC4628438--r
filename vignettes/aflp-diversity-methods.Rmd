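---
title: "Methods: replicate-based AFLP diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-based AFLP diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aflpdiver)
```

# Scope and model

`aflpdiver` analyses dominant AFLP fingerprints of clonally propagating
organisms. The underlying model is deliberately simple: the sampled
population is a mixture of clonal lineages, each lineage carries a fixed
binary band profile over the scored fragment-size loci, and an isolate's
observed fingerprint is its lineage's profile corrupted by (i) rare
genuine per-locus differences and (ii) technical noise of the AFLP assay —
fluctuating fluorescence intensity, band dropout in a replicate, and
plate-to-plate scaling. Because markers are dominant (band presence cannot
distinguish heterozygous from homozygous states), all inference is based on
profile similarity, not allele frequencies: identical profiles define a
haplotype, Dice similarity quantifies relatedness, and a bootstrap over
loci quantifies how strongly the data support each cluster.

# Band calling from dual technical replicates

Each isolate is fingerprinted twice from the same DNA extraction. A band is
called present iff

    max(i1, i2) >= t_high   and   min(i1, i2) >= t_low

with `t_high = 100` RFU (confident signal) and `t_low = 50` RFU (the
minimum reliably distinguishable from background). This closed form is
equivalent to the verbal rule "present if both replicates exceed 100, or
if they disagree with one above 100 and the other above 50" — the test
suite proves the equivalence by exhaustive enumeration over an intensity
grid spanning all threshold regions.

Two boundary decisions were genuinely open and are resolved as follows:

* **Inclusive thresholds.** The verbal rule says "greater than 100" for
  presence but "less than 100" for absence, leaving a signal of exactly
  100 undefined. Both thresholds are implemented as inclusive (`>=`).
  Fluorescence values are effectively continuous, so the choice is
  immaterial in practice, but it must be fixed for reproducibility and is
  configurable through `scoring_thresholds()`.
* **Missing records are zero.** Peak exports routinely omit absent bands,
  so a locus absent from both of an isolate's replicates is treated as
  intensity 0/0, not as an error. A locus present in exactly *one*
  replicate's records, however, indicates a malformed table and is
  rejected with the isolate and locus named.

# Locus repeatability filtering

Fragment reproducibility is the recognized weakness of restriction-site
markers, and published AFLP panels are routinely reduced to a small
repeatable core (hundreds of polymorphic loci down to a few dozen) before
analysis. The reduction criterion is rarely operationalized in print, so
the package makes its three components explicit and logs them separately
per locus:

* `conflict_fraction <= max_conflict` (default 0.05): the share of
  isolates with a *strong* replicate disagreement — one replicate at or
  above `t_high`, the other below `t_low`. Mid-zone disagreements are not
  counted as conflicts because the calling rule itself adjudicates them;
  only signals on opposite sides of both thresholds indicate an
  irreproducible locus.
* polymorphism (default required): monomorphic loci carry no information
  for Dice distances or haplotypes.
* plate-control consistency (default required when a control is given):
  one isolate is re-run on every 96-well plate; a locus on which its call
  changes between plates reflects plate-specific artefacts, not biology.

Whether the original reduction also used the plate control is not
documented; providing both criteria with separate logging reproduces the
intent while keeping each decision auditable. The filter is idempotent and
never reorders or drops isolates.

# Dice distance

For binary profiles, with `a` shared presences and `b`, `c` one-sided
presences, distance is `1 − 2a/(2a + b + c)`. Shared absences are ignored:
under dominant scoring a shared missing band is weak evidence of identity
(it may arise from any allelic state without the restriction site). Two
all-zero profiles are given distance 0 — they are *observationally*
identical, consistent with the haplotype definition — with a strict mode
(`all_zero = "error"`) available, since reference implementations differ
and the convention for this degenerate case is not documented anywhere
authoritative. Alternatives such as Jaccard or simple matching are
deliberately not offered as defaults; Dice is the standard coefficient for
this assay.

# UPGMA, locus bootstrap and consensus

`upgma()` implements classic size-weighted average linkage; node height is
half the merge distance, so trees are ultrametric by construction (verified
to 1e-9 in tests against an independent naive implementation and against
`hclust(method = "average")`). Ties are broken deterministically: clusters
are labelled by their lexicographically smallest member and the smallest
label pair merges first. This matters because identical profiles produce
exact zero-distance ties, and input-order-dependent tie-breaking (as in
some established programs) would make bootstrap supports irreproducible.

`bootstrap_support()` resamples **loci** (characters) with replacement —
the appropriate resampling unit for a fingerprint of one collection —
recomputes distances and the UPGMA tree, and scores each clade of the
full-data tree by the percentage of replicate trees containing exactly that
leaf set. Supports are reported on the full-data tree (primary output,
easiest to compare) and on the majority-rule (>50%) consensus tree
(secondary, mirroring conventional bootstrap-consensus practice). The
consensus is assembled directly from the clade frequencies: majority
clades from a single tree set are pairwise compatible, so they nest by
containment; the result is cross-checked against `ape::consensus()` in the
test suite. Consensus trees are heightless (topology + support only), and
their Newick output therefore carries no branch lengths.

**Significant clusters.** No universal bolding criterion exists for
"significant" bootstrap clusters; the package defaults to support ≥ 95%
and always reports the threshold alongside the count. One subtlety:
isolates with *identical* profiles coalesce at height zero in every
replicate, so a group of n clones would contribute n−1 trivially
100%-supported binary nodes. `count_significant_clusters()` therefore
collapses equal-height merges into polytomies before counting, so each
identical-profile group counts as (at most) one cluster and the count
reflects genuine hierarchical structure. With this rule, a noise-free
simulation of k well-separated lineages yields exactly k significant
clusters: each lineage clade persists in every locus resample, while the
higher groupings of lineages flip between resamples and fall below the
threshold.

# Haplotypes

A haplotype is a maximal set of isolates with identical calls at every
retained locus — exact identity, no tolerance, because shared fingerprints
are interpreted as clonal identity. A Hamming-radius tolerance
(`max_mismatch > 0`, single-linkage closure) exists purely for sensitivity
analysis. With the all-zero-distance convention above, haplotype grouping
coincides exactly with the Dice-distance-zero equivalence, a property the
tests assert. Sharing summaries report, per haplotype, the areas, crops and
origins of its members, flagging haplotypes that span areas or include
external-origin isolates.

# Frequency tests

Counts of isolates cross-classified by area and crop are tested with the
plain Pearson chi-square statistic (no Yates correction, matching standard
practice for these data): r×c homogeneity with expected counts from the
margins, and one-way goodness-of-fit against uniform expectation.
Small-expected-cell conditions are logged as messages but never alter the
statistic. On the motivating survey's printed 3×3 table the homogeneity
test gives χ² = 56.8770 (df = 4) and the crop goodness-of-fit gives
χ² = 12.8636 (df = 2), both matching the published values to four decimals.
The published by-area figure for the same survey could **not** be
regenerated from the printed margins under either formulation (uniform
goodness-of-fit on 34/71/27 gives 25.4091); the package reports its own
computation and treats the printed figure as an unresolved discrepancy
rather than a target.

# The synthetic-data generator

`simulate_aflp()` emulates the statistical structure the analysis assumes,
with defaults fixed once to the motivating study design: 93 isolates from
78 clonal lineages, 30 retained loci, dual technical replicates on 3
plates with a shared control isolate, 3 areas × 3 crops, and no habitat
association (`association_strength = 0`, the structure the motivating
study concluded). Per-band intensities are log-normal — strictly positive
and right-skewed like real fluorescence — with median 800 RFU for present
bands and 10 RFU for background (log-sd 0.4), placing presence far above
`t_high` and background far below `t_low`; plate effects are shared
multiplicative log-normal factors (log-sd 0.1) so the control-isolate
filter has something to detect; dropout replaces a present band's signal
with a background draw independently per replicate (default probability
0.02), which is exactly the event that exercises the scoring rule's
disagreement branch and the conflict filter; and isolates differ from
their lineage by independent per-locus flips (default 0.005–0.01 scale;
0.01 used). The intensity scale, dropout and mutation rates are
plausibility choices — no intensity distributions are published for the
motivating data — and are documented rather than fitted.

Because the table invariant requires unique (isolate, replicate, locus)
keys, the control isolate's re-runs on other plates appear under
plate-suffixed alias ids (`ISO001.p2`, ...). `aflp_diversity()` consumes
the aliases for the control-consistency filter and then drops them, so the
control contributes once to distances, trees and haplotypes.

What the generator does **not** emulate: electrophoretic size-calling
error, co-migration (homoplasy) of different fragments into one size bin,
sequence evolution within lineages, and non-multiplicative plate
artefacts. Passing tests on synthetic data therefore demonstrate that the
pipeline recovers the truth of this generative model — clean lineage
recovery in the noise-free limit, graceful degradation under dropout — not
that real fingerprints satisfy the model.

`simulate_contingency()` generates multinomial area×crop tables:
independent margins at `association = 0` (the null used for the
Monte-Carlo type-I calibration of the chi-square test) and a
matched-diagonal mixture for simple alternatives.

# Numerical and reproducibility choices

* All stochastic functions take explicit integer seeds and restore the
  caller's RNG state; identical config + seed gives byte-identical
  pipeline artifacts, and the pipeline derives per-stage seeds from the
  global one so stages can be rerun in isolation.
* Newick branch lengths are written with up to 10 decimals (trailing zeros
  stripped), so topology and heights round-trip well past the 6-decimal
  precision of the PHYLIP distance interchange format.
* PHYLIP's 10-character name limit is enforced with an explicit renaming
  map; silent truncation is refused because it can collide ids.
* UPGMA tie-breaking, child ordering, and haplotype numbering (first
  occurrence) are all deterministic, for stable diffs and tests.

# Problem sizes used in the shipped checks

The test suite exercises matrices up to ~40 isolates with 50–200 bootstrap
replicates, oracle comparisons on all seeded distance matrices of size ≤ 7,
and a 10,000-table Monte-Carlo calibration of the chi-square test at the
survey's total count (n = 132). The acceptance script runs the full
pipeline at the study scale (93 isolates, 30 loci, 1000 bootstrap
replicates). These sizes were chosen as representative of the intended use
case — isolate collections of tens to low hundreds.

# Known limitations

* Bootstrap support on 30 loci is intrinsically weak; with few characters
  the resampling variance is large and deep structure rarely reaches 95%.
  This is a property of the data type, not of the implementation.
* The haplotype definition has no missing-data state: the scoring rule
  always produces 0 or 1. Data with genuine missing codes must be resolved
  before import.
* The UPGMA implementation is O(n³) in pure R; it is comfortable for
  hundreds of isolates but not for thousands.
* `aflp_diversity()` tests frequency distributions of the *analyzed*
  isolates; survey-level count tables (which may include isolates excluded
  from fingerprinting) should be tested directly with
  `chi2_contingency()` / `chi2_goodness_of_fit()`.
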