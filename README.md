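# tmtde

Multi-batch TMT proteomics normalization and moderated differential
expression, as a tidyverse-native R package.

## The problem

Tandem-mass-tag (TMT) experiments quantify ten samples per mass-spectrometry
run via reporter-ion intensities. Studies that span several runs ("plexes")
carry two layers of technical structure: per-channel loading/labeling
effects and protein-specific per-plex batch effects. A common design — the
one this package targets — reserves two channels per plex for a pooled
reference (an equal mixture of that plex's eight experimental samples) and
crosses two factors into four groups (male/female x control/nicotine: MC,
FC, MN, FN) with two biological replicates per group per plex, n = 4 per
group over two plexes.

`tmtde` is for proteomics analysts who need that whole path as tested,
scriptable code: MaxQuant-dialect protein-group parsing and row filtering;
three-stage normalization (sample-loading scaling, trimmed mean of M-values,
then internal reference scaling or linear-model batch removal); QC (CV,
Pearson, PCA); moderated differential testing; overlap accounting between
comparisons; gene-set over-representation; and MCODE dense-cluster detection
on interaction networks. A seeded synthetic-data generator reproduces the
study design with known ground truth, so every stage is verifiable end to
end without any raw data.

## The statistic at the core

For a contrast of groups A vs B the per-protein statistic is the moderated

    d = (mean_A − mean_B) / (se + s0),       s0 = 0.5 (log2 scale)

where `se` is the pooled two-sample standard error; at `s0 = 0` this is the
classic pooled t. Significance is calibrated by label permutation (group
sizes preserved; for 4 vs 4 all 70 distinct assignments are enumerated,
identity excluded): for a threshold t,

    FDR(t) = pi0 · mean_perm #{|d_perm| ≥ t} / #{|d_obs| ≥ t},   pi0 = 1,

and a protein's q-value is the smallest FDR(t) over thresholds that still
admit it; it is significant at q < 0.05. An optional one-way ANOVA prefilter
(BH, q < 0.05, across the four groups) restricts the tested universe for
noisier datasets.

## Worked example

```r
library(tmtde)

ds   <- generate_dataset(synthetic_design(n_proteins = 300, seed = 1))
dat  <- filter_rows(ds$data)
attr(dat, "filter_counts")
#>    flagged incomplete   retained
#>         18         58        242

norm <- normalize_pipeline(dat, batch_method = "irs")
qc_report(norm)
#> # QC report
#>   mean CV by group: FC 15.3%, FN 14.9%, MC 15.9%, MN 14.7%, pool 2.4%
#>   pairwise Pearson: 0.895-1.000
#>   PCA variance explained: 42.3%, 14.0%, 9.3%

suite <- run_pairwise_suite(norm, test_config(anova_enabled = FALSE, seed = 1))
glance(suite)
#> # A tibble: 3 × 7
#>   comparison n_tested n_significant  n_up n_down n_permutations exhaustive
#> 1 MC_vs_FC        242            25    16      9             69 TRUE
#> 2 FN_vs_FC        242            24     9     15             69 TRUE
#> 3 MN_vs_MC        242            26    14     12             69 TRUE

truth_confusion(ds$truth, suite$MC_vs_FC, "MC_vs_FC")
#>   contrast    tp    fp    tn    fn   fdr sensitivity
#> 1 MC_vs_FC    25     0   270     5     0       0.833
```

Reading: of 300 simulated proteins, 18 decoy/contaminant rows and 58 rows
with a missing channel are removed. After normalization the pooled-reference
channels sit at ~2% CV (the biological groups at ~15%, reflecting the
simulated within-group spread). Each contrast tests 242 proteins with all 69
non-identity label assignments; the sex contrast calls 25 proteins, all of
them true (empirical FDR 0), recovering 25 of the 30 injected sex effects —
the 5 misses are mostly rows lost to missing-value filtering.

Overlap between the two nicotine contrasts, the way cross-comparison
convergence is summarized:

```r
tidy(overlap_summary(
  significant_proteins(suite$FN_vs_FC),
  significant_proteins(suite$MN_vs_MC)
))
#>   n_a n_b n_common n_same_direction ... pct_of_a pct_of_b pct_same_of_common
#> 1  24  26        3                2 ...     12.5     11.5               66.7
```

`autoplot(suite$MC_vs_FC)` draws the volcano plot; `autoplot(qc_report(norm),
"pca")` the PCA. The full four-dataset study (simulate → normalize → QC →
compare → overlap → enrich → cluster, with all intermediates and a manifest)
is one call:

```r
run_all(pipeline_config(out_dir = "tmtde_out", seed = 1))
```

or from a shell, `Rscript inst/scripts/run_pipeline.R run --out tmtde_out
--seed 1` (a default YAML config ships in `inst/extdata/`).

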