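# circaweld

Cross-platform concatenation and circadian rhythmicity analysis of
gene-expression time series.

## The problem

Circadian experiments sample a transcriptome every few hours after
synchronization, and rhythm detection gets markedly more reliable with
longer series — yet most real datasets cover barely one cycle. Often the
same biological system has been profiled twice on different platforms: a
microarray series (bounded log2 intensities) and an RNA-seq series (counts,
with a much wider log2-CPM dynamic range), over overlapping but different
time windows. circaweld harmonizes such a pair and welds it into one longer
series with replicated time points, then detects 24-h rhythmic genes,
compares circadian parameters across platforms, and tests gene sets for
phase clustering. It is written for computational biologists doing circadian
meta-analysis of legacy expression data.

## What it computes

* **Preprocessing** — TMM scaling factors and log2 CPM for counts (via
  edgeR), mean-expression filters (mean CPM ≥ 0.5; mean log2 intensity
  ≥ 3) with renormalization on the retained genes, and feature-to-gene
  collapse by highest mean expression.
* **Harmonization** — Training Distribution Matching: a global monotone
  map, fitted on pooled values, that clamps the count platform's log2 CPM
  by the reference's quartile-relative tail spreads and rescales onto the
  intensity range. Each platform is then normalized per gene to its mean
  over the shared time window (12–24 h) on the linear scale and the series
  are concatenated; samples at equal times become replicates.
* **Rhythm detection** — fixed-period cosinor regression
  `y(t) = m + a·cos(ωt) + b·sin(ωt)`, ω = 2π/24, per gene; amplitude
  `A = √(a²+b²)`, peak phase `φ = atan2(b,a)/ω mod 24`, relative amplitude
  `A/m`; F-test against the intercept-only model, Benjamini–Hochberg
  adjustment, significance at `q < 0.05` and `A/m ≥ 0.1`.
* **Cross-platform comparison** — Jammalamadaka–SenGupta circular
  correlation of phases, Pearson correlation of relative amplitudes, and
  mean per-time-point expression correlation on shared times.
* **Phase set enrichment** — Kuiper test (`V = D⁺ + D⁻`) of member phases
  against the uniform circle, with the Stephens small-sample correction,
  phases rounded to the full hour, a 5-rhythmic-member size filter, and BH
  control across tested sets; vector-average pathway phases.
* **Synthetic truth** — a two-platform simulator (Gaussian noise on bounded
  log2 intensities; negative-binomial counts) with known per-gene rhythm
  parameters, plus recovery scoring (sensitivity, realized FDR, circular
  phase error).

## Worked example

```r
library(circaweld)

cfg <- default_config(out_dir = "demo_run", seed = 1L)
cfg$simulate$n_genes <- 3000
res <- run_pipeline(cfg)
#> [simulate] 3000 genes, 600 rhythmic
#> [preprocess] expressed genes: intensity 2903/3000, counts 3000/3000
#> [harmonize] 2903 common genes, 20 concatenated samples
#> [rhythm] significant genes: intensity 534, counts 222, concatenated 552
#> [corr] 200 genes rhythmic on both platforms
#> [psea] 23/50 sets tested, 11 enriched
#> [recovery] sensitivity 0.893, FDR 0.029

res$recovery$median_phase_error_h
#> [1] 0.3787055
res$correlation$intensity_vs_concat$circular_r
#> [1] 0.9893514
```

Reading the output: of 600 planted rhythmic genes, the 9-sample intensity
platform alone recovers 534 significant genes and the 11-sample count
platform 222, while the 20-sample concatenated series recovers 552 with a
realized false discovery rate of 2.9% — the longer welded series detects
more true rhythms than either platform alone. Fitted peak phases on the
concatenated data are within ~23 min (median) of the planted phases and
agree with the intensity-only phases at circular correlation 0.99. Ten of
the eleven enriched gene sets are the planted phase-clustered ones (one
borderline null set slips through at q just under 0.05 in this seed).

All intermediate tables (platform matrices, three rhythm tables,
correlation report, enrichment table, recovery metrics, manifest with
checksums) are written to `demo_run/`. The same run is available from the
shell via the thin wrapper in `inst/cli/circaweld.R`.

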