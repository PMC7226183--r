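---
title: "Cross-platform concatenation and circadian analysis of expression time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform concatenation and circadian analysis of expression time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaweld)
```

## The problem

Dense circadian time courses are expensive, so a single experiment rarely
covers the two full cycles that rhythm detection ideally wants. Legacy data,
however, often exists twice for the same biological system: an older
microarray series and a newer RNA-seq series, with overlapping but not
identical sampling windows. circaweld welds such a pair into one longer time
series and analyzes its circadian structure, with every stage validated on
synthetic data whose rhythmic truth is known.

The two platforms are not directly comparable. Microarray intensities arrive
RMA-style as bounded log2 values (roughly 0 to 13.5), while RNA-seq counts,
once converted to log2 counts per million (CPM), span a much wider dynamic
range (roughly -8 to 15). The package's harmonization stage removes this
dataset shift before the series are joined.

## The model

For a gene with linear-scale abundance $y$ observed at hours $t$ after
synchronization, the fixed-period cosinor model is

$$y(t) = m + a\cos(\omega t) + b\sin(\omega t) + \varepsilon,
\qquad \omega = 2\pi/24,$$

fitted by ordinary least squares. The derived quantities are the amplitude
$A = \sqrt{a^2 + b^2}$, the peak phase
$\varphi = \operatorname{atan2}(b, a)/\omega \bmod 24$ (so the fitted curve
is $m + A\cos(\omega(t-\varphi))$), and the relative amplitude $A/m$, which
is dimensionless and only meaningful on a positive linear scale.
Significance comes from the F statistic of the harmonic model against the
intercept-only model with $(2, n-3)$ degrees of freedom; p-values are
Benjamini-Hochberg adjusted across genes, and a gene is called 24-h rhythmic
when $q < 0.05$ **and** relative amplitude $\ge 0.1$. Replicate observations
at equal (or circadianly equivalent) times enter the regression as
independent measurements, which is exactly how concatenation adds power.

The fit is plain OLS by design: it is exactly reproducible and its null
distribution is known. An iteratively-reweighted robust variant was
considered and rejected as the default because its tuning constants would
dominate the comparison between platforms; robustness against single
outliers is instead provided by the replicate structure of the concatenated
series.

## The workflow

`run_pipeline()` executes the stages in order; each is exported on its own.

1. **Preprocess.** Counts get TMM scaling factors and are filtered at mean
   CPM $\ge 0.5$ over all time points, then renormalized (TMM and CPM
   recomputed) on the retained genes; intensities are filtered at mean log2
   intensity $\ge 3$. Both boundaries are inclusive ("at least"). When a
   platform reports multiple features per gene, `collapse_features()` keeps
   the feature with the highest mean over all time points (ties broken to
   the lexicographically smallest feature id, for determinism).
2. **Harmonize.** Training Distribution Matching (`fit_tdm()` /
   `apply_tdm()`) is fitted on the pooled values of the commonly expressed
   genes: the reference's tail spreads relative to its inter-quartile range
   define clamp bounds on the target, and the clamped values are rescaled
   linearly onto the reference range. The map is global and monotone, so
   within-gene and within-sample rank structure is untouched. The rescaling
   uses the observed extremes of the clamped data, so the transformed
   platform spans the reference range exactly.
3. **Normalize and concatenate.** Each platform is mapped to the linear
   scale and every gene is divided by its mean over the samples in the
   shared window (12-24 h inclusive by default). The division is per gene,
   not global: a single global constant could not remove gene-specific
   platform offsets. Division happens on the linear scale because the
   rhythm fit consumes linear values. `concatenate_series()` then pools the
   samples (default designs: 9 intensity samples 0-24 h and 11 count
   samples 12-42 h, giving 20 samples over 0-42 h with 12-24 h doubly
   observed). Samples at circadianly equivalent but distinct wall times
   (0 h vs 24 h; 12/15/18 h vs 36/39/42 h) keep their wall times — the
   24-h-periodic model makes them effective replicates without relabeling.
4. **Detect rhythms.** `rhythmicity_table()` on each platform alone (on its
   original linear values) and on the concatenated series.
5. **Compare platforms.** `correlation_report()` restricts to genes
   significant in both inputs and reports the Jammalamadaka-SenGupta
   circular correlation of phases (with its asymptotic normal p-value), the
   Pearson correlation of relative amplitudes, and the mean per-time-point
   Pearson correlation of expression over the shared window (replicate
   pairs correlated pairwise and averaged).
6. **Phase set enrichment.** `run_psea()` asks, per gene set, whether the
   phases of its significantly rhythmic members cluster on the circle,
   using the Kuiper statistic $V = D^+ + D^-$ against a uniform background
   with the Stephens small-sample correction
   $\lambda = (\sqrt{n} + 0.155 + 0.24/\sqrt{n})V$ and the asymptotic
   series p-value. Member phases are rounded to the full hour (half-up,
   24 mapping to 0) before testing; sets with fewer than 5 rhythmic members
   are excluded, and BH adjustment runs across tested sets only (excluded
   sets produce no p-value, so they do not count toward $m$). The reported
   vector-average phase of a set uses the unrounded phases: rounding is a
   property of the test input, not of the phase estimate.

## The synthetic data generator

`simulate_truth()` plus `render_intensity()`/`render_counts()` emulate a
two-platform study with known truth. Signals are pure single-harmonic
cosines on the linear scale — matching the fitted model, deliberately:
recovery scores then measure the pipeline, not model mismatch. Damping and
progressive desynchronization of real cultures are not simulated, so
passing recovery tests says nothing about robustness to those; the
generator's job is to make correctness testable, not to imitate biology in
full.

Defaults and why:

* baseline log2 abundance $\sim N(7, 2)$ clamped to $[0.5, 13]$ — spans the
  bounded intensity envelope;
* 20% of genes rhythmic, relative amplitudes uniform on $[0.2, 0.6]$,
  phases uniform on the circle;
* intensity noise: additive Gaussian, sd 0.15 log2 units, values clamped to
  $[0, 13.5]$ — the standard array noise model inside the platform's range;
* counts: negative binomial with dispersion 0.05 and expected count
  `library_size * s(t)/sum(mesor)`, library size $2\times10^7$ per sample —
  typical bulk RNA-seq depth and biological-replicate-level dispersion.
  Neither platform's true noise magnitude is knowable a priori; these are
  the package's fixed study conditions, exposed as profile parameters.

`simulate_gene_sets()` plants phase-clustered sets (members drawn from
rhythmic genes inside a random window) among null sets for validating
enrichment.

## Numerical choices and degenerate inputs

* Constant series: the F statistic is defined as 0 and $p = 1$; exact fits
  (zero residual with signal) give $p = 0$.
* A non-positive fitted mesor leaves the relative amplitude undefined
  (`NA`) and the gene non-significant.
* The cosinor fit requires at least 6 observations and 3 distinct times
  modulo the period; otherwise the model is unidentifiable and rejected.
* The Kuiper p-value series is truncated when terms fall below 1e-12 and
  clamped to $[0, 1]$; effective statistics $\lambda < 0.4$, where the
  asymptotic series loses accuracy, return $p = 1$ — there is no evidence
  against uniformity in that regime.
* Circular means with resultant length below 1e-9 (e.g. antipodal phase
  pairs) are reported as undefined rather than as an arbitrary direction.
* Significance uses strict $q < 0.05$ and inclusive relative amplitude
  $\ge 0.1$; expression filters are inclusive at their boundaries.
* TMM follows the published definition via edgeR (30%/5% trims,
  upper-quartile reference choice, factors centered to geometric mean 1);
  the log-CPM pseudo-count (default 0.5) is scaled per sample by effective
  library size.

## Problem sizes used in validation

The test suite and the acceptance script run the full workflow at the
default design (10,000 genes; 9 + 11 samples), multi-seed properties at
800-3,000 genes over 10-50 seeds, and Monte-Carlo calibration of the Kuiper
test at 5,000 draws of size 30 — sizes at which every statistical property
asserted (sensitivity, FDR control, phase recovery, type-I calibration,
enrichment recovery) is stable across seeds.

## Known limitations

* Only the fixed 24-h period is fitted; period scanning, multiple
  harmonics and damped models are out of scope, as are rhythm detectors of
  the JTK/RAIN family.
* TDM is the only cross-platform transform offered; quantile normalization
  or batch-correction methods are deliberately not substitutes here.
* The enrichment background is the uniform circle; empirical backgrounds
  are not implemented.
* Real platform artifacts (probe saturation beyond a hard clamp, length or
  GC bias in counts, batch structure beyond the platform shift) are not
  simulated.
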