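---
title: "Methods: multi-batch TMT normalization and moderated differential testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-batch TMT normalization and moderated differential testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtde)
```

## The problem

Isobaric-label (TMT) proteomics quantifies up to ten samples per mass-
spectrometry run through reporter-ion intensities. Studies larger than one
run split samples across several "plexes" and must then remove two kinds of
technical structure before any biology can be read off: per-channel effects
(pipetting, labeling efficiency, library composition) and per-plex batch
effects, which in TMT data are protein-specific. The design this package
targets dedicates two channels of each 10-plex to a pooled reference — an
equal mixture of the plex's eight experimental samples — and arranges the
four experimental groups (male/female crossed with control/nicotine: MC, FC,
MN, FN) as two biological replicates per group per plex, giving n = 4 per
group over two plexes.

`tmtde` implements the full quantitative path: reading MaxQuant-dialect
protein-group tables, row filtering, three-stage normalization, QC,
s0-moderated two-group tests with permutation-based FDR, cross-comparison
overlap accounting, gene-set over-representation, and MCODE dense-cluster
detection on interaction networks — plus a seeded synthetic-data generator so
that every stage is testable against known ground truth.

## Row filtering

Decoy ("reverse"), contaminant and only-identified-by-site protein groups
are removed, then any row with a missing value in any channel of the
dataset. Zero reporter intensities are treated as missing on read: a zero is
an absence of measurement, and log2 of zero would otherwise contaminate
every downstream statistic. Filtering is idempotent and never alters
surviving values; counts per reason are retained for the run manifest.

## Normalization model

Three stages, in a fixed order, each a positive scaling:

1. **Sample loading (SL).** Within each plex, channel totals (over proteins
   present in every channel of the plex) are equalized to the plex mean:
   `factor_j = mean(totals) / total_j`. Corrects global pipetting/labeling
   differences.
2. **Trimmed mean of M-values (TMM).** Within each plex, against the channel
   whose upper quartile is closest to the plex mean upper quartile. Per
   protein, `M = log2(x_j / x_ref)` and `A = 0.5 * log2(x_j * x_ref)`; the
   top and bottom 30% of M and 5% of A are discarded and the factor is 2 to
   the precision-weighted mean of surviving M (inverse delta-method variance
   weights), then factors are anchored to multiply to 1 within the plex.
   TMM is computed within plex because at this point plexes have not yet
   been aligned; the trims, weighting and reference rule are exposed as
   arguments.
3. **Batch correction**, one of two branches:
   - **Internal reference scaling (IRS)** for datasets with reliable pooled
     channels: per protein, the plex reference is the *geometric* mean of
     the plex's pooled channels (geometric, to keep log-scale symmetry);
     every channel of the plex is multiplied by `target / reference`, where
     the target is the geometric mean of the plex references. After IRS the
     pooled reference of each protein is identical across plexes, and the
     operation is idempotent. Proteins with zero/missing pool values cannot
     be scaled and are dropped (counted).
   - **Linear-model correction** for noisier datasets: on the log2 scale,
     per protein, `value = group mean + plex offset` is fit by least squares
     with sum-to-zero plex coding and the fitted offsets subtracted. Group
     structure (including the pools as their own group) is preserved
     exactly; a pure additive plex shift is removed exactly. The correction
     refuses designs where batch is confounded with group.

The IRS branch is the default for the deepest dataset of the four-dataset
study plan; the other three use the linear branch (`default_dataset_plan()`).

## Quality control

`qc_report()` summarizes a normalized dataset: per-channel quartiles,
per-group coefficients of variation, all pairwise Pearson correlations of
log2 values, and a PCA of sample profiles (protein-wise centering only, no
variance scaling, by singular value decomposition, on complete rows). CVs
are computed per protein on the *intensity* scale — `100 * sd / mean` of
`2^x` with the sample (n−1) standard deviation — because per-group CVs of a
few percent are only meaningful there; they are then averaged per group.
Single-replicate groups are skipped with a warning.

## The differential-testing engine

For a contrast of groups A vs B (reference), the per-protein statistic is

`d = (mean_A − mean_B) / (se + s0)`

with the pooled two-sample standard error (Welch available behind a flag)
and a moderation constant `s0` on the log2 scale (default 0.5). At `s0 = 0`
this is exactly the classic pooled t statistic; `s0 > 0` demands a minimum
fold change from low-variance proteins, so significance reflects both effect
size and stability.

Significance is calibrated by label permutation. Group labels are shuffled
with group sizes preserved; when the number of distinct assignments is at
most the requested 250 randomizations — as it always is for 4 vs 4, which has
70 — all of them are enumerated, excluding the identity. For a threshold t,

`FDR(t) = pi0 * mean_permutations(#{|d_perm| >= t}) / #{|d_obs| >= t}`

with `pi0` fixed conservatively at 1. A protein's q-value is the smallest
`FDR(t)` over observed thresholds that still admit it (t at or below its own
|d|), which makes q monotone non-increasing in |d|; it is significant when
`q < 0.05`. Permutation counts are aggregated by their mean (median behind a
flag). Two-sided throughout; no correction is applied across the three
pairwise contrasts, which are reported separately.

An optional prefilter runs a one-way fixed-effects ANOVA across the four
groups with Benjamini–Hochberg adjustment and keeps proteins with q < 0.05
before pairwise testing; the filtered universe is what the pairwise tests
see. It is enabled for the three lower-coverage datasets of the default plan
and disabled for the deepest one. Proteins constant across all samples have
an undefined F and d and are dropped before testing.

The three study contrasts are MC vs FC, FN vs FC and MN vs MC, each with the
second group as reference, so a positive log2 fold change always means
"higher in the first-named group".

## Benchmarks and what they show

Two operating checks are packaged as functions because they define what the
engine's numbers mean:

- `fdr_null_benchmark()`: 50 seeded simulations of the full design with no
  true effects, normalized and tested at defaults. The mean per-run
  empirical false-discovery proportion estimates the probability of any
  false discovery and should sit at the nominal 0.05 up to binomial noise.
  With 69 usable permutations and ~170 tested proteins the estimator's
  discreteness leaves it slightly above 0.05 on average — visible only as a
  small excess within the binomial error band.
- `recovery_benchmark()`: exact 1.0 log2 sex and treatment effects on 10% of
  proteins at within-group sd 0.25; pooled sensitivity and empirical FDR
  over the three contrasts. Missing cells are disabled here so the number
  measures the detection method rather than row filtering, and the ANOVA
  prefilter is off in both benchmarks so the permutation engine itself is
  what is measured (with the prefilter on, a pure-null run retains almost
  nothing and the check would be vacuous).

Both run in seconds at the packaged problem sizes (50 runs x 200 proteins;
5 runs x 3 contrasts).

## Cross-comparison overlap

`overlap_summary()` intersects two significant lists by gene symbol
(upper-cased; accession fallback when the symbol is empty), splits the
shared set by direction concordance, and reports the common count as a
percentage of each list and the concordant count as a percentage of the
common set. Exact values are stored; reported percentages use
round-half-away-from-zero to one decimal, the convention that reproduces
printed summary percentages from their integer counts.

## Over-representation analysis

`enrich()` is a one-sided hypergeometric upper tail `P[X >= k]` of a query
list against each gene set, inside a stated universe. The default universe
is all quantified proteins after filtering — the natural background for a
proteomics experiment, narrower than the genome background a web service
would default to; the universe is an explicit argument precisely because
this choice moves p-values. Sets are intersected with the universe first;
sets with empty intersection are untestable and excluded from the BH
denominator. Up- and down-regulated lists are tested separately and the
report keeps at most the top five sets under q < 0.05 — possibly none, which
is a valid outcome, not an error.

## MCODE cluster detection

Networks are built from score-filtered edge lists (combined score >= 0.7 by
default, the customary high-confidence cutoff); self-loops and duplicate
undirected edges are resolved on load. Vertex weight is the core number of
the highest k-core of the vertex's closed neighborhood times that core
subgraph's density; vertices below the degree cutoff (default 4) weigh 0.
Seeds are visited in decreasing weight order and clusters grow breadth-first
(depth <= 100), admitting unvisited neighbors with weight at least
`seed_weight * (1 − 0.2)`.

One admission rule is this package's own tightening: once a cluster has two
or more members, a candidate must be adjacent to at least two of them. With
the classic weight-only rule, two dense complexes joined by a single bridge
edge merge into one cluster whenever the bridge endpoints' weights clear the
threshold (in two bridged 5-cliques every vertex weighs 4.0, so expansion
walks straight across); requiring two independent attachments makes a lone
bridge edge insufficient, and the bridged 5-cliques resolve into the two
5-clique clusters one would draw by hand. The rule is deterministic,
documented here, and shared by the brute-force reference implementation the
tests compare against on random graphs.

Haircut (default on) iteratively removes singly-connected vertices;
candidates whose highest k-core falls below 4 are discarded; cluster score
is `density x node count` on the induced simple subgraph
(`density = 2E / (V(V−1))`); ranking is by score, then size, then
lexicographically smallest member, so output is fully deterministic. The
interaction-score threshold is the only edge gate — the 1% FDR a web service
reports alongside its networks concerns its enrichment display, not edge
inclusion, and has no counterpart here. Cluster annotation is delegated to
`enrich()` on each cluster's member list.

## The synthetic-data generator

`synthetic_design()` fixes the study layout (2 plexes x 10 channels, 2
replicates per group per plex, 2 pools per plex) and draws, per protein:
log-normal base abundance (log2 mean 20, sd 1.5, mimicking reporter-ion
dynamic range), sparse signed effects (10% of proteins per contrast, |effect|
~ N(1.0, 0.25) log2), a per-protein per-plex batch shift (N(0, 0.4) log2 —
exactly the structure IRS removes), per-channel loading factors (2^N(0,
0.25))), and cell-level noise N(0, 0.25) log2. Pooled channels are the
loading-scaled arithmetic mean of the plex's eight experimental pre-loading
intensities with their own technical noise (0.05 log2, matching the
few-percent CVs pooled references show in practice). Decoy and contaminant
rows (3% each) and 1% missing cells are appended. Everything is reproducible
from one integer seed.

What it does not emulate — and therefore what passing tests cannot claim
about real data: peptide-to-protein rollup, ratio compression from co-
isolation, intensity-dependent missingness (missingness here is completely
at random, which is harmless because rows with any missing value are
filtered), and correlated protein modules. The noise and effect-size values
are simulation conventions chosen once for realism, not estimates from any
particular dataset.

## Orchestration and determinism

`run_all()` executes simulate → filter → normalize → QC → compare → overlap
→ enrich → cluster for the four-dataset plan, writing every intermediate as
TSV plus a YAML manifest of parameters, seeds and row counts at every
filter. All randomness flows from one root seed through fixed per-dataset
and per-stage offsets. Each stage recomputes from the *persisted* text
tables rather than in-memory copies, so a full run and a stage-wise re-run
over the same files are byte-identical — the written representation is the
source of truth, which costs one re-read per stage and buys exact
reproducibility (text round-trips of doubles are stable from the first
rewrite onward). `run_stage()` re-runs any single stage against those files;
a thin Rscript wrapper (`inst/scripts/run_pipeline.R`) exposes the same
stages as shell subcommands with distinct exit codes per error class.

Problem sizes packaged for routine runs: 300 proteins per dataset by
default, 200 in the benchmark suites and 80–200 in the test fixtures —
small enough to iterate on, large enough for stable statistics.

## Numerical choices and degenerate inputs

- Zero intensities are missing; negative intensities are rejected on the
  raw/normalized scales.
- Ties in TMM trimming are handled by midranks; the reference channel's own
  factor is exactly 1 before anchoring.
- `FDR(t)` uses exact >= counting (no interpolation); ties in |d| receive
  identical q-values, so duplicated rows test identically.
- Equal group means give d = 0 regardless of s0; groups of fewer than two
  values are an error, as is a contrast with fewer than two distinct label
  assignments.
- Percentages are rounded half away from zero only at the reporting
  boundary; internal values stay exact.
- Empty enrichment reports and empty cluster sets are valid results; empty
  queries, universes and collections are errors.

## Known limitations

- The permutation-FDR estimate is granular at 69 permutations; q-values
  below 1/69 are not resolvable, and the null benchmark documents a small
  finite-sample excess over the nominal level.
- IRS consumes pooled channels; designs without pools must use the linear
  branch.
- The linear batch branch assumes additive (log-scale) batch effects; batch-
  by-group interactions are not modeled.
- Gene-symbol matching (first symbol of a multi-entry group, case-folded) is
  a convention; protein groups whose symbols collide are rejected rather
  than merged in overlap inputs.
- Enrichment results on the bundled synthetic gene sets are plumbing
  demonstrations; biological conclusions require real annotation files
  (GMT) and a considered universe.
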