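---
title: "Methods: subtype signatures and their regulatory analysis"
author: "regsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype signatures and their regulatory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(regsig)
```

This vignette documents the models, parameter choices and numerical
conventions behind `regsig`, and what the synthetic-cohort tests do and do
not establish about real data.

# The analytical setting

The package targets expression cohorts of tumors assigned to molecular
subtypes (the motivating system is urothelial carcinoma with Urobasal A/B,
Genomically Unstable and SCC-like classes, in cohorts with strong group
imbalance such as 131/21/85/29). Three questions are addressed:

1. Which genes characterize a subtype (up/down signatures; co-expression
   modules)?
2. Are the promoters of a signature enriched for binding of particular
   transcription factors, and is that binding spatially organized?
3. Do per-tumor summary scores (HOX switch score, marker ratios) and
   histological measurements (mitotic division angles) order tumors along
   the differentiation axis those factors define?

# Coordinates and input conventions

All genomic intervals are 0-based half-open (the BED convention); the
annotation loader accepts a 1-based dialect behind a `one_based` flag,
default off, so a single internal convention prevents off-by-one drift.
The gene universe is one record per gene: the longest transcript, with
ties broken by the lexicographically smallest `(chrom, txStart)` so the
choice is invariant to input row order. The TSS is `txStart` on `+` and
`txEnd - 1` on `-`.

Expression matrices are log scale. Rows are restricted to genes present in
the annotation when one is supplied. Where several rows map to one gene,
the row with the largest interquartile range is kept: no collapse rule is
canonical here, and IQR is a variance-robust default used by common array
tooling; it is deliberately a loader option, not hidden behavior. Missing
values are rejected by default (`impute = "median"` opts into per-gene
median imputation), never silently filled.

# Promoter windows and the binding matrix

Promoter windows span −5000 to +1000 bp around the TSS. On the minus
strand the window is mirrored about the TSS
(`[tss − 1000 + 1, tss + 5000 + 1)`), so it covers the same
transcription-relative positions and keeps length exactly 6000 bp;
windows are clamped at position 0 and at the chromosome end when sizes
are known. "Bound" means at least `min_overlap` (default 1) bp of overlap
between a peak and the window; a peak overlapping several windows counts
once in each, since each promoter is a separate observational unit for
the enrichment tests. Multiple peak files for one factor (different cell
contexts) add their counts by default; a per-context OR on the bound flag
is available (`combine = "or"`). Overlap computation delegates to
GenomicRanges; a brute-force all-pairs scan in the test suite verifies
exact agreement.

# SAM: two-class signatures at FDR 0

The per-gene statistic is the relative difference
`d = (mean2 − mean1) / (s + s0)`, with `s` the pooled standard error of
the mean difference and `s0` a fudge factor selected from the percentile
grid of `{s_i}` (0, 5, …, 100th) to minimize the coefficient of variation
of the median absolute deviation of `d` across `s_i` strata — ties resolve
to the smallest grid index, so the estimate is deterministic. Signatures
are derived one-vs-rest per subtype, which matches the directional
(up/down) per-subtype lists the analysis needs; multiclass SAM is out of
scope.

Sample labels are permuted (all distinct assignments when there are at
most `n_permutations` of them, otherwise that many random draws from a
seeded stream). Sorted permuted statistics give the expected order
statistics; a threshold Δ defines cut points (the smallest observed `d`
whose excess over its expected order statistic reaches Δ on the up side,
mirrored on the down side), and every gene beyond a cut point is called.
The FDR estimate at Δ is `π0 · F(Δ) / calls(Δ)` with `π0` the interquartile
null-fraction estimate capped at 1 and `F` a summary of the per-permutation
false-call counts. The returned Δ is the smallest candidate whose estimate
meets the target.

**Why the mean false-call summary is the default.** The original SAM
procedure averages the number of falsely significant genes over the
permutations, and that choice matters at target FDR 0: with a *median*
summary, FDR 0 only requires that half the permutations produce no call
beyond the cut points, and on pure-noise data the top-ranked gene clears
that bar roughly half the time — a 1000 × 40 noise matrix then yields
spurious "FDR 0" calls in over half of runs. With the *mean* summary an
FDR of exactly 0 requires that **no** permutation anywhere in the null
ensemble exceeds the cut points, which is the behavior a user asking for
"FDR 0" wants: on the same noise matrices, 0 genes are called in 50/50
seeds, while 50 genes planted at a 3-SD shift (20 vs 20 samples) are
recovered completely with no false calls. `false_count = "median"` and
`"q90"` remain available.

# QT clustering under jackknife correlation

Similarity between genes is the jackknife correlation: the minimum Pearson
correlation over all leave-one-sample-out deletions, which prevents a
single outlier sample from carrying a cluster. The default cutoff 0.4 is
read as a similarity floor; reading it as a diameter bound under
`d = 1 − r` is the same algorithm with floor `1 − cutoff`
(`cutoff_type = "diameter"`). Note the two classic growth rules — adding
the gene that maximizes the cluster's minimum similarity, and adding the
gene that minimally increases the diameter — coincide exactly under
`d = 1 − r`, so no separate "diameter growth" code path exists.

The classic QT scheme applies: every remaining gene seeds a greedily grown
candidate; the largest candidate is emitted and removed; iteration stops
when the largest candidate is smaller than `min_size` (default 15). All
ties are deterministic: growth ties resolve to the smallest gene index;
among equally large candidate clusters the one with the **larger minimum
pairwise similarity** wins, then the smaller seed index. Quality-first
tie-breaking is deliberate: with a correlation floor as permissive as 0.4
and cohort-sized sample counts, a background gene whose chance correlation
to a tight module just clears the floor can form an equally large
candidate that omits one true member; preferring the tighter cluster
resolves such ties toward the genuine module rather than by input order.
Genes are row-standardized before clustering (a no-op for Pearson
correlation, kept for numerical hygiene); zero-variance genes must be
filtered by the caller, and the code errors rather than guessing.

Within the orchestrated pipeline, clustering is restricted to the
`qtc.max_genes` (default 500) most variable genes, the usual practice for
a quadratic-cost procedure; `qt_cluster()` itself has no such cap.

# Binding enrichment: Fisher and resampling

For a query signature and a factor, the one-tailed Fisher test is the
upper hypergeometric tail `P(X ≥ n_bound_query)` on the binding-matrix
universe (platform-mapped genes; the full annotation is a caller choice).
The resampling test draws `n_resamples = 100000` gene lists of equal size,
uniformly without replacement — plain gene-label sampling, with no
expression- or GC-matching — and evaluates two statistics per draw: the
bound-promoter count and the total peak count. Empirical p-values use the
add-one convention `(1 + #{draw ≥ observed}) / (n_resamples + 1)`: they
are never zero, the floor `1/(n_resamples + 1)` is explicit, and ties
count toward the tail (conservative).

A calibration property worth stating precisely: the bound-count statistic
is integer-valued, so under a true null `P(p ≤ α)` sits *below* α by up to
half the probability step at the α-quantile of the null distribution. The
calibration test therefore uses the most continuous configuration
available at its scale (a half-bound universe of 2000 with a half-universe
query), where the exact expected fraction of `p ≤ 0.05` is 0.0456; looser
designs can sit visibly lower without any defect in the sampler.

# Colocalization profiles

For every anchor-factor peak overlapping a query-gene promoter, offsets to
all other-factor peak midpoints within ±1000 bp are histogrammed in 50-bp
bins. Peak position is the interval midpoint (integer floor) — summit
columns, when present in the source BED, are a documented alternative the
loader ignores by default. Each (anchor, other) peak pair counts once; a
peak shared by two promoters is not double-counted, because pairing is
between peaks, not promoter instances. The profiles are descriptive (no
test on profile shape), matching how such metaplots are used.

# HOX switch score and marker ratios

Each HOX gene row present in the matrix is standardized across samples;
the score is the mean anterior z (HOXA1–7, HOXB2–8) minus the mean
posterior z (HOXA9–13). Several constructions could express an
anterior-versus-posterior balance; this z-mean-difference is the package's
documented choice: it is affine-invariant per gene, symmetric (swapping the
lists negates it), and rank-orders a cohort along the anterior/posterior
switch. HOXA8 and HOXB1/HOXB9+ are excluded by default per the printed
anterior/posterior ranges; both lists are arguments. Zero-variance rows
are dropped with a warning rather than failing a whole cohort. Marker
ratios on log-scale data are differences of means of log expression
(numerator minus denominator genes), reported with their antilog.

# Division-angle test

Mitoses are stratified by distance to the basal membrane in cell layers;
"basal" is layer 0 by default (`basal_max_layer` configurable, since
"close proximity" has no canonical numeric reading). For a group's basal
angles the observed median is compared with medians of 10⁴ equally sized
angle sets drawn from the null; `p_high` is one-sided toward 90° with the
add-one convention. The default null is uniform on [0°, 90°] — the natural
isotropy reference when angles are measured in the section plane. Two
alternatives are built in: `"pooled"` (resampling the pooled observed
angles, for testing a stratum against the study's own angle pool) and
`"sine"` (3D-isotropic orientations projected to a section). Medians for
even n are the mean of the two central order statistics.

# Synthetic cohorts and what the tests show

Every generator is a pure function of its parameters and a seed; one
master seed fans out to per-generator Lehmer sub-streams so adding a
generator never perturbs existing draws. Defaults encode the study
conditions the pipeline is meant to face: a four-group cohort with
131/21/85/29 imbalance; signatures planted at 3 SD; promoter binding at
0.2 baseline versus 0.6 in the enriched set; a 20-gene co-expression
module from a shared latent factor with residual SD 0.3 (expected
pairwise r = 1/(1 + 0.09) ≈ 0.92, comfortably above the 0.4 floor); an
anterior/posterior HOX gradient at ±2 SD; and basal division angles from
a normal truncated to [0°, 90°] (mean 85°, SD 8° in the bundled study)
against uniform non-basal angles.

The generators emulate planted *signal structure*, not array physics:
there are no batch effects, probe saturation, correlated noise across
background genes, or heavy-tailed measurement error. Passing tests
therefore establish that the statistics recover what they are defined to
recover, at the default parameter settings, under clean noise — they do
not certify performance on any particular real cohort, where probe
quality and normalization dominate.

Problem sizes in the test suite and the acceptance script are chosen to
make each check sharp but quick: SAM null/power at 1000 genes × 40
samples over 50/10 seeds with 200 permutations; calibration at 2000
trials × 2000 resamples; planted enrichment at the full 100 000 resamples;
exhaustive QT-cluster verification at ≤ 12 genes where subset enumeration
is feasible; the pipeline fixture at 400 genes with reduced resample
counts (a fixture configuration choice — the package defaults are
unchanged).

# Known limitations

- SAM is two-class only (no paired, survival or multiclass variants), and
  no per-gene q-values are produced — only the global Δ/FDR machinery the
  signature derivation needs.
- The greedy QT growth is the classic heuristic; it is verified exhaustively
  on small instances, but on adversarial similarity structures a grown
  candidate can in principle miss a larger admissible subset.
- Resampling enrichment draws uniform gene lists; if a signature's genes
  are atypical in covariates that also predict binding (expression level,
  GC, promoter CpG class), the null is optimistic by construction.
- Peak files are consumed as called intervals; no signal-level processing,
  peak calling, or enhancer/distal assignment is attempted.
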