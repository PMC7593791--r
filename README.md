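# clubnet

Rich-club and diverse-club analysis of brain functional connectomes in R.

Resting-state fMRI studies of the Alzheimer's disease spectrum
(subjective cognitive decline, amnestic mild cognitive impairment)
summarize each subject's brain as a 90-region network and ask where the
disease strikes first: the *rich club* — the most highly connected
regions and their mutual links — or the *diverse club* — the regions
whose edges are spread most evenly across the network's communities.
`clubnet` packages that entire analysis for anyone working with
parcellated time series: network construction, small-world metrics with
degree-preserving null normalization, club definition and connection
strengths, overlapping-node metrics, and covariate-adjusted group
statistics, plus a seeded synthetic-cohort generator so the whole
pipeline is testable without any imaging data.

## The method in brief

Per subject, Pearson correlations between the 90 AAL regional time
series are binarized at sparsities S = 5%…50% (step 5%), keeping only
positive edges. Per threshold the package computes Cp, Lp, Eg, Eloc and
their null-normalized forms γ = Cp/⟨Cp_rand⟩, λ = Lp/⟨Lp_rand⟩,
σ = γ/λ against Maslov–Sneppen degree-preserving random networks
(1000 by default), summarizing each curve by its area under the curve.
At S = 15% the rich club is the top 13 (15%) regions by healthy-control
mean degree and the diverse club the top 13 by healthy-control mean
participation coefficient `pc_i = 1 − Σ_s (k_is/k_i)²` (Louvain
consensus communities). Edges are classified as club / feeder / local,
and connection strengths sum the retained correlation weights per class.
Group contrasts are age- and sex-adjusted ANCOVAs with
Bonferroni-corrected pairwise t-tests; behavioral relevance is assessed
with age/sex-partial correlations against MMSE, GDS and logical-memory
scores.

## Worked example

Simulate a small cohort (12 controls, 8 SCD, 12 aMCI; the default
disease effect attenuates hub–hub connectivity to 0.9/0.7 of the
control level) and run the full pipeline:

```r
library(clubnet)
clubnet_cli(c("simulate", "--seed", "7", "--out", "demo-cohort",
              "--n-per-group", "12,8,12"))
clubnet_cli(c("run", "--cohort", "demo-cohort", "--out", "demo-results",
              "--seed", "7", "--n-null", "50", "--community-runs", "20"))
read_clubs("demo-results/clubs.json")
```

This run (about 90 s) prints/writes:

```
$rich_club    INS.L, ROL.L, ACG.L, STG.R, INS.R, ACG.R, PreCG.L, PoCG.L,
              CAU.L, PreCG.R, PoCG.R, ROL.R, STG.L
$diverse_club INS.L, ROL.L, STG.R, ACG.L, TPOmid.R, SMG.L, ORBinf.R,
              OLF.L, TPOsup.R, CAU.R, TPOmid.L, STG.L, IPL.L
$overlap      ROL.L, INS.L, ACG.L, STG.L, STG.R
```

i.e. the 13-region clubs recover the planted hub and connector sets, and
their overlap contains the four planted overlap regions (INS.L, ACG.L,
ROL.L, STG.R). `demo-results/stats.tsv` holds the group statistics; the
key planted effect is detected:

```
metric              contrast     stat  value   p_raw   p_bonferroni
rich_club_strength  HC:SCD:aMCI  F     6.030   0.0068  —
rich_club_strength  HC:aMCI      t     3.108   0.0055  0.0166
auc_sigma           HC:aMCI      t    -2.269   0.0345  0.1035
```

(the rich-club connection strength of the aMCI group is reduced relative
to HC, significant after Bonferroni correction; small-worldness shows
the same direction). `demo-results/metrics.tsv` holds per-subject metric
AUCs — e.g. group-mean λ-AUC ≈ 0.47 and σ-AUC ≈ 0.68–0.74 over the
0.45-wide sparsity interval.

The same analysis is available programmatically:

```r
spec <- cohort_spec(seed = 7)          # default: 28 HC / 19 SCD / 29 aMCI
cohort <- generate_cohort(spec)
an <- analyze_at_sparsity(cohort, with_pc = TRUE)   # single-threshold core
res <- run_pipeline(pipeline_config("demo-cohort", n_null = 50,
                                    community_runs = 20, seed = 7,
                                    output_dir = "demo-results"))
```

## Layout

`R/` implementation; `tests/testthat/` unit, property and acceptance
tests; `vignettes/clubnet-methods.Rmd` the methods vignette (model,
generator design, numerical choices); `exec/clubnet` the CLI wrapper;
`scripts/acceptance.R` the acceptance report.
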