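---
title: "Scoring, filtering and assembling phylogenomic loci with phylosieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, filtering and assembling phylogenomic loci with phylosieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosieve)
```

## The problem

Concatenating every available locus into one supermatrix is rarely the
best way to resolve a contentious node. Large matrices amplify
systematic bias along with signal: fast-evolving loci saturate,
long-branched taxa attract each other regardless of history, and
sparsely sampled loci contribute mostly missing data. phylosieve
implements the curation stage that sits between orthology
inference/alignment and tree inference: score every locus on a small
set of diagnostics, discard or down-weight the pathological ones, and
assemble reduced matrices that are both information-rich and small
enough for site-heterogeneous models.

The package assumes you already have, per locus, a trimmed amino-acid
alignment and a gene tree with branch lengths (typically an ML tree,
optionally with bootstrap labels). Everything downstream — scoring,
filtering, ranking, concatenation, resampling, recoding, hypothesis
mapping — is covered here.

## The per-locus scorecard

`score_loci()` computes five diagnostics per locus. For a locus with
alignment $A$ over taxa $S$ and gene tree $T$:

* **Occupancy and missing data.** `n_taxa` counts taxa with at least
  one non-missing residue; `pct_missing` is the percentage of missing
  cells over the *full roster* × length grid, with absent taxa counted
  as all-missing rows. The roster convention makes locus-level and
  supermatrix-level missingness additive: the missingness of a
  concatenation is exactly the length-weighted mean of its members'.
  The missing alphabet is `-`, `?`, `X` (case-insensitive), matching
  trimAl/RAxML conventions.

* **Rate of evolution.** The mean branch length of the gene tree:
  total tree length divided by the number of edges, internal and
  terminal. Binary-rooted serializations are first reduced to their
  unrooted form (the two root-adjacent branches merge), so the same ML
  tree gives the same rate however a program chose to write it.

* **Saturation.** Ordinary least squares (intercept included) of
  uncorrected p-distances on patristic distances over all usable taxon
  pairs. p-distances use pairwise deletion: a site counts for a pair
  only when both taxa carry a non-missing residue, and pairs with no
  comparable site are dropped listwise. An unsaturated locus is close
  to linear; multiple substitutions flatten the relationship, so a low
  slope and low $R^2$ flag saturation.

* **Information content.** The arithmetic mean of the numeric support
  labels on internal nodes. Support scales are detected per file at
  read time: if every numeric label lies in $[0,1]$ the file is taken
  to be on the posterior-probability scale and rescaled to percent, so
  bootstrap and Bayesian inputs are comparable. Loci whose trees carry
  no labels get `NA`, and any filter or ranking that needs support
  then fails loudly rather than silently skipping them.

* **Long-branch (LB) score.** For taxon $i$, let $PD_i$ be its mean
  patristic distance to all other taxa and $\overline{PD}$ the mean of
  the $PD_i$. Then

  $$LB_i = \left(\frac{PD_i}{\overline{PD}} - 1\right) \times 100.$$

  Scores are percent deviations and average to zero over the taxa of
  a tree by construction — a property every tree is tested against at
  tolerance $10^{-9}$.

## Comparing LB scores across loci: the mode ranking

LB scores are taxon-specific, so loci cannot be ranked by raw values.
`lb_mode_ranking()` instead fixes a small set of *focal* taxa —
lineages suspected of long-branch artifacts — and, for each, pools its
LB scores across all loci where it occurs, then locates the mode of
that distribution with a Gaussian kernel density estimate (Silverman's
bandwidth, argmax over a 512-point grid spanning the observed range;
a zero-variance pool degenerates to its single value). A locus earns
one point per focal taxon present whose score is at or below the
taxon's mode: high counts mark loci in which the focal taxa are *not*
unusually long-branched. At least 10 loci per focal taxon are required
before a mode is trusted.

Two numerical choices deserve note. "At or below the mode" uses a
small tolerance ($10^{-9}$) so a point-mass distribution counts its
own mode. And whether the historical implementations used a histogram
or a KDE is immaterial to the package's contract: the KDE was chosen
because it is deterministic under fixed defaults and has no binning
parameter.

A caution learned from simulation: planting a *single* long focal
branch in a locus inflates $\overline{PD}$ for that tree and thereby
*depresses* the LB scores of every other taxon, including the other
focal taxa — enough to raise, not lower, the count of a planted locus.
The count discriminates cleanly when the focal lineages are
long-branched jointly, which is the situation the diagnostic targets
(outgroups plus a handful of fast ingroup lineages, long together or
not at all). The package's validation suite plants focal taxa jointly
for this reason.

## Spurious-sequence screening

`flag_spurious()` implements the pre-curation screen for
mis-assembled or non-orthologous sequences: a taxon is flagged when
its terminal branch is more than `factor` (default 5) times the mean
branch length of its gene tree. The mean includes the candidate's own
branch, and the inequality is strict. The screen is single-pass;
flagged taxa are reported, not removed iteratively with recomputed
means, because iterating changes the semantics of "the average for
the tree" and in practice the flagged set is small.

## Filtering, ranking, and the matrix family

`filter_loci()` applies conjunctive thresholds with the boundary
semantics of the curation rules they encode: minimum occupancy is
inclusive ("at least N taxa"), the missing-data cap discards only loci
*strictly* above it ("more than 40%"), and the support threshold is
inclusive by default with a strict variant available, since the two
phrasings ("60 or more" vs "higher than 60") both occur in common
usage.

`rank_and_select_best()` builds composite scores: each locus is ranked
on occupancy, average support, rate (lower is better), saturation
slope (steeper is better) and focal-under-mode count; the composite is
the unweighted sum of ranks (weights configurable), and the best
$\lceil f \cdot n \rceil$ loci are kept. Ranking by slope rather than
$R^2$ is the package default because the slope has a direct
interpretation (observed divergence per unit inferred distance) and a
monotone relationship with saturation severity; both statistics are in
the table for users who prefer otherwise. Ties within a criterion
share average ranks; composite ties break lexicographically by locus
name, so selection is deterministic.

The assembly family then follows:

* `concatenate()` — supermatrix over a fixed roster, `?`-filled
  blocks for absent taxa, partition table tiling `1..L` in ascending
  locus-name order (1-based inclusive coordinates, RAxML style).
* `progressive_series()` — nested sets of the $k$ slowest-evolving
  loci (default sizes 5, 10, 15, 20, 30, 50, 100, 200, 300, 500), for
  tracing how support responds as faster loci are added.
* `rate_bins()` — consecutive non-overlapping slices of the
  rate-sorted locus list (e.g. ten 108-locus bins from 1080 loci);
  a non-divisible remainder goes to the final, shorter bin, trading
  equal bin size for complete coverage.
* `jackknife_replicates()` — fixed-size locus resampling without
  replacement, byte-reproducible from a single seed.
* `recode()` — reduced amino-acid alphabets: Dayhoff-6
  (AGPST / DENQ / HKR / ILMV / FWY / C), Dayhoff-4 (AGPST / DENQ /
  HKR / FWYILMV, cysteine treated as missing — the exact group
  composition of the 4-state scheme varies among implementations, and
  this is the convention adopted here), and hydrophobic/polar
  (ACFGILMVW / DEHKNPQRSTY). Groups map to representative letters so
  recoding is idempotent; missing symbols pass through.

Rate ties everywhere break by locus name, keeping series and bins
deterministic.

## Hypothesis support and Bayes-factor comparison

`bipartition_support()` reports the percentage of trees in a set
containing a given unrooted split — the natural way to map support for
competing hypotheses (say, "ctenophores sister to all other metazoans"
vs "ctenophores with cnidarians") over bootstrap, jackknife or binned
analyses. Trees whose leaf set differs from the roster are errors, not
silently restricted, because restriction changes what a split means.

`bayes_factor_compare()` consumes two marginal log-likelihoods — a
constrained hypothesis and its negation, typically from stepping-stone
integration — and reports the absolute difference in log units plus a
verdict on the standard interpretation scale applied to twice the
difference: above 10, very strong; 6–10, strong; 2–6, positive; below
2, barely worth mentioning. The thresholds are arguments, since
published tables sometimes derive the doubled quantity differently
than their printed likelihoods imply. Marginal-likelihood estimation
itself is out of scope; only the comparison arithmetic lives here.
`steppingstone_generations()` does the run bookkeeping (e.g. 50 stones
× 5000 generations − 1 burn-in stone = 245,000 usable generations).

## The simulator: what it emulates, and what it does not

`simulate_locus_set()` generates locus collections with the structure
the toolkit assumes: one shared species tree; per-locus rate
multipliers (log-normal by default, or supplied); variable occupancy
via taxon dropout; cell-level missingness; and optionally planted
long-branch taxa. Sites evolve independently under the equal-rates
20-state process (all exchanges equal, uniform frequencies), whose
divergence curve has the closed form
$p(t) = \tfrac{19}{20}(1 - e^{-20t/19})$ — chosen precisely because
that closed form lets the simulator itself be validated against
expectation. Returned trees are the *true* scaled trees, not
re-inferred ones: gene-tree estimation is out of scope, so statistics
that would consume ML trees are exercised on truth, and rate recovery
is exact up to dropout-induced pruning.

A plant of scale $s$ sets the taxon's pendant branch to $s$ times the
tree's mean branch length, rather than multiplying whatever pendant
length the random tree happened to draw. Plant severity is thereby
expressed on the same scale the 5× spurious filter tests against: an
8× plant is unambiguously a long branch to a 5× filter, which is what
"planting a long branch" should mean. Optional synthetic bootstrap
labels (`node_support_range`) can be attached so support-dependent
stages run end to end; they are uniform noise and carry no signal.

Defaults mirror a realistic study design: 36 taxa, 1080 loci, locus
lengths 150–600 columns, 5% cell missingness plus 20% taxon dropout
(about a quarter of the full grid missing overall). What the simulator
does **not** emulate: empirical exchangeabilities or compositional
heterogeneity, among-site rate variation, indels, alignment or
trimming error, and gene-tree estimation error. Passing tests
therefore demonstrate that the *statistics and bookkeeping* are
correct, not that the diagnostics would behave identically on real
data, where tree error and model misspecification add noise the truth
trees lack.

## Problem sizes and numerical conventions

The test suite and the reproduction script run the generator at
reduced sizes chosen to exercise every code path with comfortable
statistical power: 300 loci on 20 taxa (lengths 80–120) for parameter
recovery, 100 single-plant loci for filter power, 1000 random trees
for the LB identity, 500 random regressions against the closed-form
OLS oracle, and a 1080-locus collection on 24 taxa (lengths 60–100)
for the end-to-end scoring and best-10% selection. These sizes are
the package's own validation design; the functions themselves have no
size limits beyond memory.

Other conventions, gathered in one place: patristic distances are
computed by tree traversal (`ape`) and are root-invariant; OLS always
includes an intercept; a regression needs at least 3 usable pairs and
non-degenerate x; `rank()` uses average ties within criteria;
partition coordinates are 1-based inclusive; taxon labels are
whitespace-sanitized to underscores on write, with collisions an
error; and all stochastic operations take explicit integer seeds.

## Known limitations

Occupancy-weighted rate corrections are not attempted: the mean branch
length is comparable across loci only to the extent their taxon sets
overlap, which is the same approximation its original use accepted.
The LB mode ranking inherits KDE boundary behavior when a focal
taxon's score distribution is sharply truncated. And the interleaved
PHYLIP and NEXUS dialects are deliberately unsupported — FASTA and
relaxed sequential PHYLIP cover the intended pipelines.
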