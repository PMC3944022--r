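---
title: "Clonality concordance of paired primary and metastatic tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonality concordance of paired primary and metastatic tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpair)
```

## The question and the procedure

For a cohort of patients with a resected primary carcinoma and a matched
metastasis, `clonalpair` asks, pair by pair: does the metastasis descend
from the dominant clone of the primary (linear progression), or from a
genetically distinct lineage (polyclonal progression)? The procedure is
deliberately rule-based rather than probabilistic, mirroring how such
cohorts are analyzed in practice when sample sizes are small (tens of
pairs) and the evidence is categorical:

1. **Copy-number relatedness.** Somatic copy-number segments of every
   tumor sample are reduced to a binned genome-wide profile; samples are
   clustered agglomeratively; a pair counts as *adjacent* iff its two
   samples are dendrogram siblings (their first merge joins exactly the
   two singletons). Siblinghood is a deliberately strict criterion: being
   "in the same subtree" would depend on an arbitrary cut height, whereas
   siblinghood is parameter-free and reproducible.
2. **Mutation-level relatedness.** Mutations are matched by the identity
   key `chrom:pos:ref:alt`. A driver panel is screened for genes carrying
   an identical non-silent key in both samples; the Jaccard shared
   percentage is carried alongside as continuous evidence.
3. **Reconciliation.** `related` = adjacent and ≥ 1 shared driver;
   `distinct` = neither; anything else is `discordant_evidence`. In the
   reference cohort bundled with the package the two streams agree
   perfectly (8 of 15 related), but a total classification rule must
   handle disagreement, hence the third label instead of a forced call.
   The shared percentage never enters the rule: the reference cohort
   itself contains a pair sharing 52% of mutations whose copy-number
   profiles and driver genes are nevertheless discordant, and the
   classifier reports that tension in its evidence string rather than
   resolving it.

### Assumptions

* Mutation tables are already called and annotated (gene symbol, effect
  class); segment tables are already segmented with integer total copy
  number and an LOH flag. The package does no alignment, calling, or
  annotation.
* Inputs are consistently normalized upstream: indel keys use `"-"`
  alleles and no left-normalization is attempted, so the same indel
  represented two ways will not match.
* Segments of one sample do not overlap (the SEG convention). Overlapping
  segments are tolerated arithmetically (their deviations add) but are not
  meaningful.
* One primary and one metastasis per patient; sample identifiers are
  globally unique.

## SCNA categories and the burden summary

Integer copy number and the LOH flag map to five categories under the
standard diploid reading: 3 → one copy gain, ≥ 4 → high copy gain, 1 →
one copy loss, 0 → homozygous loss, and 2 + LOH → copy-neutral LOH. The
copy-number class takes precedence over the LOH flag. These thresholds are
the package's own convention (segmentation software rarely documents its
internal equivalents); they are centralized in `categorize_segment()`.

`summarize_scna()` counts *segments* (events), not bases, and its
`total_scna` is the sum of the four copy-number categories with
copy-neutral LOH excluded. That convention is validated in the test suite
against all 30 rows of the bundled reference burden table: every printed
total equals the sum of its four copy-number columns.

## The binned copy-number matrix

`build_cnv_matrix()` tiles each chromosome into `bin_size` windows
(default 1 Mb, conventional for array-resolution CNV clustering) and
computes the per-base mean deviation from diploid: each base contributes
`copy_number − 2` summed over covering segments, zero where uncovered, and
the bin value is the average over the bin length. Treating uncovered bases
as diploid (rather than averaging only over covered bases) means a bin 1%
covered by a gain looks 1% gained, not fully gained — partial coverage is
attenuated, which is the desired behavior for distance computation. A
parallel layer holds the fraction of each bin covered by LOH segments and
is appended to the profile at weight `loh_weight` (default 1) before
distances are taken. The implementation is verified against a per-base
brute-force oracle on toy genomes.

## Clustering and determinism

`hierarchical_cluster()` implements the standard agglomerative algorithm
with complete (default), average, or single linkage via the
Lance–Williams update. The distance metric is Euclidean by default
(Manhattan and correlation are available); the linkage choice dominates
the metric for this application, and all three linkages are validated
against an independently coded naive agglomerator that recomputes every
inter-cluster distance from scratch, and against `stats::hclust` through
cophenetic equality.

The reason for implementing the agglomerator rather than delegating to
`stats::hclust` is tie-breaking: when two candidate merges are at exactly
the same distance, the pair whose cluster creation indices are
lexicographically smallest merges first (singletons numbered by input
order, later clusters by merge order). Ties at bit-identical distances do
occur with integer-valued copy-number profiles, and an undocumented
tie-break would make sibling calls irreproducible across platforms. The
result is an ordinary `hclust` object, so `cutree()`, `cophenetic()` and
Newick export via `ape` all apply.

No bootstrap support values are computed: the adjacency criterion is
binary, and resampling bins would impose an arbitrary dependence model.

## The shared-mutation percentage

The pair-level sharing statistic is the Jaccard form

$$\mathrm{shared\ pct} = 100 \cdot \frac{S}{n_1 + n_2 - S}$$

for $S$ shared keys among $n_1$ and $n_2$ per-sample totals (0 when both
are empty). Published tables of this statistic rarely state the
denominator; the Jaccard form is adopted here because, uniquely among the
candidates (min, mean, union), an integer $S$ reproduces *every* printed
shared percentage of the bundled reference table to within ±0.05. That
back-solving check is frozen in the test suite as the formula's oracle.
Counting for this statistic uses all seven retained effect classes
(including synonymous), while driver concordance and gene frequencies use
non-silent classes only — frequencies describe functional lesions,
whereas sharing measures lineage.

## Hypermutation and the LOH association

No consensus threshold defines hypermutation from panel-agnostic exome
counts. The package offers two strategies — absolute (count > 500) and
fold-over-median (count > 5× cohort median) — both of which flag the same
four metastases in the reference cohort, whose 819–971 mutations sit
sevenfold above every other sample (≤ 113). Flags are monotone in the
threshold by construction. The lesion screen reports mismatch-repair and
polymerase panel genes carrying ≥ 1 missense mutation, the criterion under
which exactly the hypermutated reference samples screen positive.

The association between hypermutation and copy-neutral LOH burden is a
two-sample t-test on per-sample LOH counts grouped by flag. The Welch
variant is the default: with a 4-vs-11 split and an order-of-magnitude
variance difference between groups, pooling is indefensible — on the
reference cohort the pooled p-value is two orders of magnitude weaker,
and only Welch reproduces the published association (p = 2.782e-09; both
variants remain available and are validated against a textbook-formula
oracle to a relative error below 1e-8). Degenerate zero-variance inputs
are resolved before dispatch: equal means give t = 0, p = 1; unequal
means give the limiting p = 0 with a `degenerate` flag.

The paired primary-vs-metastasis burden comparison (`paired_t()`) on the
reference cohort's eight grouped pairs yields p ≈ 0.32 — consistent with
the published conclusion of no significant difference, though not
numerically identical to the published 0.28, which a standard paired t on
the printed counts does not reproduce (the original subset or variant is
unstated). The package reports its computed value and asserts only
computability, not agreement.

## The synthetic cohort generator

`simulate_cohort()` exists so that every pipeline stage can be tested
against known truth without array or sequencing data. Defaults are
calibrated once to the reference cohort's magnitudes and are not tuning
knobs:

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_pairs` | 15 | patients | reference cohort size |
| `fraction_related` | 8/15 | — | reference related fraction |
| `trunk_mutations_mean` | 40 | mutations | back-solved shared counts (26–51) of related reference pairs |
| `private_mutations_mean` | 25 | mutations | gives per-sample totals ~65 and shared percentages 30–55% |
| `hypermutator_probability` | 4/15 | — | four of 15 reference metastases |
| `hypermutator_multiplier` | 35 | fold | lifts private burden to ~875, inside the observed 819–971 range |
| `loh_baseline_mean` / `loh_hypermutator_mean` | 15 / 150 | segments | reference LOH columns (0–80 vs 145–164) |
| `loh_dispersion_baseline` / `_hypermutator` | 0.3 / 30 | NB size | baseline LOH is strongly overdispersed; hypermutator LOH is tight |
| `scna_bins` | 200 | bins | 250 kb bins on the 5 × 10 Mb toy genome |
| `scna_event_rate` | 0.2 | per bin | tumor-like altered fraction |
| `scna_noise_rate` | 0.05 | per bin | related profiles similar but not identical |

The multiplier of 35 (rather than a round 10) is deliberate: with private
means of ~25, only a ~35-fold lift lands hypermutators in the observed
819–971 range and above the 500-count threshold, keeping the generator's
phenotype consistent with the calling convention it is meant to exercise.

Mutation keys are drawn *without replacement from one genome-wide pool*,
so unrelated samples share zero keys by construction and truth labels are
exact, not probabilistic. Related pairs share exactly their trunk
(floored at one mutation, which carries the planted driver). Hypermutator
SCNA elevation is confined to the LOH layer: the copy-number backbone
similarity (which drives adjacency) and the hypermutator phenotype remain
independent axes of truth, so a related pair with a hypermutated
metastasis is still recoverable as related — as its real counterparts
would be by driver sharing. All randomness flows through one seed in a
fixed draw order; identical configurations yield byte-identical output
files.

What the generator does **not** emulate: allele frequencies and subclonal
structure beyond the two-level trunk/private split; mutational signatures
(effects and substitution types are drawn from fixed proportions);
genome-scale segment boundaries (events are bin-aligned); germline
contamination; and any quantitative SCNA similarity scale for real arrays
— `scna_noise_rate` is a synthetic dial chosen so that recovery is
near-perfect at low noise and collapses to the chance sibling rate when
each bin is redrawn independently (`scna_noise_rate = 1`). Note that at
noise 0.5 half the backbone is still shared, which measurably preserves
adjacency; the no-signal limit is 1, not 0.5. Passing recovery tests
therefore demonstrates that the pipeline's logic is sound under the
planted statistical structure, not that it would recover clonality at any
particular accuracy on real arrays.

## Validation problem sizes

The test suite validates clustering against the naive agglomerator on 200
random matrices of up to 8 leaves for all three linkages; t-tests against
the formula oracle on 500 random inputs; the binned matrix against
per-base averaging on 10 kb toy chromosomes; and end-to-end recovery on
20 replicates of 30-pair cohorts at strong-signal defaults, requiring
≥ 95% classification accuracy, ≥ 95% adjacency sensitivity, and exact
hypermutator recovery. These sizes make the full suite run in well under
a minute per file while keeping every Monte-Carlo assertion comfortably
powered.

## Known limitations

* The classifier is rule-based; it produces no posterior probability of
  clonal relatedness and no uncertainty on the cohort fraction. A
  likelihood model of key sharing would be the natural extension.
* Dendrogram siblinghood is sensitive to cohort composition: adding or
  removing samples can break or create adjacency. The chance sibling rate
  for unrelated profiles is nonzero (order 1–2% in cohorts of dozens of
  samples), which bounds attainable specificity.
* Mutation identity is exact-key matching; inconsistently normalized
  indels or multi-nucleotide variants will under-count sharing.
* The SCNA "burden" counts segments as events; platforms that fragment
  events differently are not comparable on this scale without
  re-segmentation.
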