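---
title: "clubnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clubnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`clubnet` implements a complete functional-connectome group analysis for
parcellated resting-state time series (90 regions of the AAL atlas by
default):

1. **Networks.** Each subject's T × 90 time-series matrix yields a 90 × 90
   Pearson correlation matrix, binarized over a proportional-threshold
   grid: sparsity S = 5% to 50% in 5% steps, where S is the fraction of
   the N(N−1)/2 possible edges retained.  Only positive correlations are
   ever kept (standard practice for binarized resting-state networks; the
   number of requested edges lost to the positivity rule is logged).
   Thresholding keeps the `round(S·N(N−1)/2)` largest correlations with a
   deterministic lexicographic tie-break, so identical inputs give
   bit-identical networks.

2. **Global topology.** Per threshold: clustering coefficient Cp,
   characteristic path length Lp (mean over *reachable* ordered pairs),
   global efficiency Eg (mean inverse distance, 1/∞ = 0) and local
   efficiency Eloc.  Normalized quantities come from degree-preserving
   null networks built by Maslov–Sneppen double-edge swaps (10 × E swap
   attempts per null; 1000 nulls by default): γ = Cp/⟨Cp_rand⟩,
   λ = Lp/⟨Lp_rand⟩, σ = γ/λ.  Each metric is summarized across the grid
   by the trapezoidal area under the curve (AUC), removing the
   arbitrariness of any single threshold.  Note that an AUC over a
   0.45-wide sparsity interval is roughly half the typical point value —
   e.g. λ-AUC ≈ 0.5 when λ ≈ 1 — which is how the package reports both,
   explicitly labelled.

3. **Clubs.** At the reference sparsity (S = 0.15) the *rich club* is the
   top `floor(0.15·N)` = 13 regions by nodal degree averaged over the
   reference (healthy-control) group; the *diverse club* is the top 13 by
   participation coefficient, `pc_i = 1 − Σ_s (k_is/k_i)²`, computed
   against a seeded Louvain consensus partition per subject and averaged
   over the same reference group.  Note pc is bounded by 1 − 1/m for m
   communities; it cannot reach 1.  Every edge is then classified as
   club (both endpoints in the club), feeder (one endpoint) or local
   (neither), and per-subject connection strengths sum the retained
   correlation weights per class — so club + feeder + local strength
   always equals the network's total retained weight.

4. **Overlapping nodes.** Regions in both clubs — simultaneously
   highest-degree and highest-participation — are the candidate
   integrative core.  The three disjoint sets (overlap, rich-only,
   diverse-only) each get per-subject means of the nodal metrics
   (degree, efficiency, clustering, shortest path length, betweenness).

5. **Statistics.**  Group comparisons are ANCOVA partial F-tests of the
   group factor controlling age and sex (exact least squares), with
   age/sex-adjusted pairwise t-tests Bonferroni-corrected over the three
   group pairs (the family is per metric, not across metrics).
   Demographics use one-way ANOVA and a 2 × 3 χ² for sex.  Behavioral
   relevance uses partial correlations (residualizing both variables on
   age and sex) against MMSE, GDS, and immediate/delayed logical-memory
   scores, by default only for metrics whose group ANOVA survived
   Bonferroni, pooled over the patient groups (SCD + aMCI); a switch
   forces all correlations.

All randomness (null ensembles, Louvain restarts, synthetic cohorts)
descends from one integer seed through a documented linear-congruential
derivation, so every pipeline run is bit-reproducible.

## The synthetic cohort generator

No clinical data ship with the package.  The generator produces cohorts
with the statistical structure the analysis assumes, so every stage is
testable offline, with known ground truth.

**Latent connectome.** Each subject has a nonnegative symmetric weight
matrix built from factor loadings `W = B Bᵀ` (zero diagonal, plus small
symmetric noise, sd 0.01):

* a *global factor* (variance 0.03) — baseline between-community weight;
* five *community factors* (variance 0.35) on contiguous 18-region
  blocks — within-community weight ≈ 0.38;
* *hubs* (13 regions, default the bilateral sensorimotor/paralimbic set)
  have community and global loadings multiplied by 1.45 and load on a
  per-community hub factor (variance 0.65) plus a shared cross-community
  hub factor (variance 0.32), both scaled by the group's **attenuation**
  (HC 1.0, SCD 0.9, aMCI 0.7) — the planted disease effect on hub-hub
  connectivity;
* *connectors* (13 regions, 4 of them also hubs so the clubs have a
  planted overlap) drop their community membership and instead load
  evenly (variance 0.15) on a random **3 of the 5** community factors.

The Gram construction keeps the matrix near-PSD, which matters: the
time-series sampler shifts the diagonal to positive definiteness, and a
large shift would compress all correlations toward zero until T = 140
sampling noise swamps the planted structure.

*Why 3 of 5 communities rather than all 5:* with a global rank threshold,
connectors loading on all five community factors become strongly
mutually correlated (shared loadings act like one clique) and their
degree matches the hubs', so the degree ranking can no longer dissociate
the two planted sets.  Restricting each connector to a random subset
keeps participation high while keeping degree moderate; the evenness of
its weight mass across the loaded communities is preserved (and tested,
< 10% relative spread over plain targets).

**Time series.** T = 140 iid samples from N(0, Σ) with
`Σ = W + (shift + noise_sd²)·I`, `shift = max(|λ_min(W)| + 0.01, 2.0)`.
The fixed floor of 2.0 keeps the shift — and hence the global correlation
scale — identical for every subject.  Without it the shift tracks the
hub-factor variances, so attenuating hub-hub weights would *raise* every
other correlation of that subject and cancel most of the planted
strength effect (rank thresholding is scale-invariant; summed strengths
are not).

**Subject-level variation.**  Two independent log-normal jitters:
sd 0.08 on the hub-hub attenuation, and sd 0.15 on the whole hub
elevation (a "hub-vulnerability" axis).  The second is what gives
overlap-node connectivity — and so measured overlap path length —
biological between-subject variance rather than pure sampling noise.

**Cognition.**  The delayed-recall score is
`1.5 + 4.3 · proxy + group offset + N(0, 1)`, where the proxy is the
inverse mean latent row weight of the planted overlap nodes — a
continuous communication-distance proxy that rises exactly when the
thresholded network's overlap-node path length rises (empirically
r ≈ 0.65 between proxy and measured Lp).  The slope 4.3 was calibrated
once so that the population correlation between the score and the proxy
is ≈ 0.75, and then frozen.  Group offsets (0, −1, −10) set Table-1-like
group means (≈13.5 / 13 / 5).  Because the coupling to path length is
*positive* while the clinical offsets push the impaired group down, the
pooled across-group correlation is offset-dominated; calibration
checks of slope recovery therefore run cohorts with offsets at 0, which
isolates the planted coupling.  Ages are Normal(71, 5) truncated to
[55, 90]; sex is Bernoulli(0.5); MMSE/GDS/immediate-recall are group-mean
normals.

**What a green test does and does not establish.**  The generator
emulates modular correlation structure, hub degree concentration,
connector participation, a hub-targeted group effect, and a
network-coupled cognitive score.  It does not emulate hemodynamics,
autocorrelated noise, motion, site effects, or negative correlations;
green tests certify the *pipeline* (recovery, calibration, determinism),
not any claim about real cohorts.

## Numerical choices and edge cases

* Disconnected graphs: Lp averages reachable pairs only; efficiencies
  use 1/∞ = 0; isolated nodes have clustering 0, pc 0, nodal Lp 0
  (flagged).  This keeps all metrics finite at the 5% sparsity end.
* Thresholding ties break by ascending (row, column) index; club-ranking
  ties break by atlas order with a logged warning.
* Betweenness is Brandes' exact algorithm normalized by (N−1)(N−2)/2.
* The Louvain consensus uses the majority (>0.5) co-assignment graph's
  connected components, falling back to the best-modularity run if the
  consensus is degenerate; everything is seeded and deterministic.
* ANCOVA guards: rank-deficient designs error naming the collinear
  columns; a covariate set that already fits the response perfectly
  returns F = 0, p = 1; partial correlations error on (numerically)
  zero-variance residuals.
* Missing cognitive scores exclude a subject from that correlation only,
  with a logged count.

## Known limitations

* Weighted-network generalizations, the φ(k) rich-club coefficient
  curve, permutation/FDR inference, and overlapping communities are out
  of scope.
* Single-threshold club definitions follow the reference analysis
  (S = 0.15); the config exposes the threshold but no multi-threshold
  club consensus is attempted.
* The per-community/cross-community hub-factor split means the group
  attenuation leaves a small un-attenuated hub-hub baseline
  (boosted-global share ≈ 0.06 of ≈ 0.7–1.0 weight).
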