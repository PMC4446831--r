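# regsig

Regulatory analysis of tumor subtype gene signatures.

Molecular subtypes of urothelial carcinoma (Urobasal A/B, Genomically
Unstable, SCC-like) differ in the transcription-factor circuitry wired into
their expression programs. `regsig` implements the statistical core of that
kind of study as a reusable, tested R pipeline:

- **Signature derivation.** Two-class Significance Analysis of Microarrays
  (SAM): the moderated statistic *d* = (x̄₂ − x̄₁)/(s + s₀) per gene, expected
  order statistics and false-call counts from label permutations, and the
  smallest threshold Δ whose estimated FDR = π₀·(mean permuted false calls)/
  (observed calls) meets the target (the subtype signatures use target
  FDR 0). Co-expression modules come from quality-threshold (QT) clustering
  under jackknife correlation — the minimum leave-one-sample-out Pearson
  correlation — with a similarity floor of 0.4 and a minimum cluster size
  of 15 genes.
- **Promoter binding.** Strand-aware promoter windows (−5000/+1000 bp around
  each RefSeq TSS, longest transcript per gene), ChIP-Seq peak-to-promoter
  mapping (≥1 bp overlap, via GenomicRanges), and a genes × factors binding
  matrix.
- **Enrichment.** One-tailed Fisher's exact test (upper hypergeometric tail)
  plus a resampling test comparing a signature against 100 000 random gene
  lists of equal size on two statistics at once — bound-promoter count and
  total peak count — with add-one empirical p-values. Also generic
  hypergeometric gene-list overlap and co-binding ("bound by ≥ k factors")
  summaries.
- **Spatial structure.** Colocalization profiles: histograms of other-factor
  peak-midpoint offsets within ±1000 bp of an anchor factor's peaks in
  signature promoters.
- **Scores.** A per-tumor HOX switch score — mean z of anterior HOXA1–7 /
  HOXB2–8 minus mean z of posterior HOXA9–13 — and marker log-ratios (e.g.
  FABP4/5 vs CRABP2).
- **Division angles.** A resampling test comparing the median basal mitotic
  division angle with medians of 10⁴ random angle sets (uniform-orientation
  null), one-sided toward 90°.
- **Synthetic cohorts.** Generators for annotation, peak files, expression
  cohorts, and mitosis records with planted, parameterized ground truth, so
  the whole pipeline is exercisable and testable without any downloads.

## Worked example

Simulate a four-subtype cohort with a 40-gene signature planted down in the
SCC-like group, one transcription factor enriched at its promoters
(bind rate 0.6 vs 0.2 baseline) and one control factor, then run the full
pipeline:

```r
library(regsig)

sim <- simulate_study("study", seed = 21, n_genes = 400,
                      groups = c(UroA = 30, UroB = 8, GU = 20, SCCL = 12),
                      n_signature = 40, n_mitoses = 80)
sim$config$params[["enrichment.n_resamples"]] <- 2000
sim$config$params[["sam.n_permutations"]]     <- 150
sim$config$params[["qtc.max_genes"]]          <- 100
out <- run_pipeline(sim$config)

read.delim(file.path(out, "enrichment_summary.tsv"))
#>   signature  factor query_size n_bound_query     fisher_p resampling_p_bound resampling_p_peaks
#> 1 SCCL-down  TF_ENR         41            21 4.303935e-05       0.0009995002        0.008995502
#> 2 SCCL-down TF_CTRL         41             6 8.912971e-01       0.8990504748        0.821089455

read.delim(file.path(out, "angle_tests.tsv"))
#>   group  n observed_median null_median_mean  null_lo  null_hi    p_high n_resamples
#> 1  UroA 40        83.83583         45.05371 31.85639 58.30214 9.999e-05       10000
```

SAM at target FDR 0 recovered the planted down-signature (41 genes called,
including all 40 planted); its promoters are strongly enriched for the
planted factor — 21/41 bound, Fisher p ≈ 4·10⁻⁵, resampling p ≈ 10⁻³
(2/(R+1): one random list in 2000 matched the observed binding) — while
the control factor is null on both tests. The basal division-angle test
detects the planted near-90° bias at the empirical floor 1/(10⁴+1): the
observed median of 83.8° is far above the uniform null band (32–58°). The
output directory also holds the binding matrix, QT clusters, per-sample
HOX scores, colocalization profiles, and a run-metadata JSON recording
seeds and parameters.

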