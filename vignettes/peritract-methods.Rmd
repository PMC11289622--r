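---
title: "Methods: peri-tract expression, recording quality, and the biomarker screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-tract expression, recording quality, and the biomarker screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peritract)
```

## The problem

Chronically implanted cortical microelectrodes trigger a foreign body
reaction — reactive astrogliosis, microglial activation, and neuronal loss —
that reshapes the tissue within a few hundred micrometres of the device and
is suspected to drive the decline of recording quality over weeks.
`peritract` implements an analysis pipeline that links spot-based spatial
gene expression around the electrode tract to extracellular recording
quality and histology: annular binning of expression by distance from the
tract, depth normalization, differential expression between the
electrode-site region and naive-matched tissue, the standard SNR / MUA / LFP
signal-quality algorithm, and a regression screen that nominates genes whose
electrode-site expression tracks those outcome metrics.

Every stage is exercised against a seeded synthetic-data module with known
ground truth, so the pipeline's statistical behaviour (calibration, power,
formula recovery) is testable without the study's deposited sequencing data.

## Spatial geometry

Spots are assigned to annuli of width 100 µm (10 µm for
immunofluorescence-intensity profiles) by their centroid distance from the
tract. Bins are half-open `[k·w, (k+1)·w)`: a centroid exactly on a bin edge
belongs to the upper bin, and the electrode-site cluster (radius 300 µm,
i.e. bins 0–2) uses the matching strict upper bound `d < 300`. The tract is
a point (its centroid) by default; a polygon outline is supported, in which
case distance is measured to the nearest outline edge and is zero inside —
the faithful choice when the tissue interface, not the centroid, is the
reference. Naive-matched regions are either user-supplied coordinates or
seeded random 300 µm discs whose centres are drawn uniformly over the
spot-occupied area and rejected until pairwise centre distances exceed twice
the radius; anatomical matching by hand is out of scope.

Radial profiles divide per-annulus counts by annulus area (analytic for a
point tract, grid-integrated for polygons) for neuronal density, or average
pixel values whose centres fall in the annulus for intensity; empty
intensity bins are recorded as missing rather than zero. The within-300 µm
summary used to pair histology with recording metrics is the area-weighted
mean over the covered bins, which for densities equals total count over
total area.

## MNA normalization

Depth normalization follows the median-normalized-average convention: within
the selected cluster each spot's counts are scaled by
`median(cluster totals) / spot total`, so every normalized spot total equals
the cluster median total, and a gene's MNA is the arithmetic mean of its
normalized counts over the cluster. The scaling direction equalizes depth
(the literal reading of "multiplying by the ratio of the total counts of
that spot and the median" would amplify deep spots, which cannot be the
intent of a depth normalization). Zero-total spots cannot be normalized and
are dropped with a warning. Two invariants are asserted in the tests:
normalized totals are constant within a cluster to 1e-6 relative tolerance,
and MNA profiles are exactly invariant to a global rescaling of the raw
counts.

Quality control mirrors standard practice for this assay: mean UMI per spot
must reach 50 000 (configurable), and the raw counts of the housekeeping
genes *Gapdh* and *Actb* are regressed on per-spot totals — a consistently
expressed gene should track sequencing depth, so a low R² flags a capture
anomaly. The pass threshold (R² ≥ 0.5) is a configuration default, not a
literature value.

## Differential expression

The two-cluster test is an sSeq-style negative-binomial conditional exact
test, written for this package:

1. **Low-count filter.** A gene is kept only if its mean raw count reaches
   1 in at least one cluster.
2. **Size factors.** `s_j = total_j / median(totals over both clusters)`.
3. **Dispersions.** Method-of-moments per gene on size-corrected counts,
   `max(0, (v - m)/m²)` with `v` the pooled within-cluster variance, shrunk
   toward the panel mean with a James–Stein-type weight. The weight compares
   the between-gene spread of raw estimates to their expected sampling
   variance (delta method, normal approximation to the sample variance), so
   with hundreds of genes and little true spread the estimates collapse to
   the pooled value.
4. **Exact test.** Conditional on the gene's pooled count `T`, cluster sums
   are modelled as negative binomial with moment-matched mean and variance
   (`q·S`, `q·S + φ·q²·Σs²`); the two-sided p-value sums the probabilities
   of all splits of `T` no more likely than the observed one. Above a pooled
   count of 900 the test switches to a conditional-normal approximation with
   continuity correction; the two branches agree within 0.01 on matched
   moderate-tail cases, which is also where p-values matter (near p = 0.5
   the enumerated p itself moves in discrete steps larger than that).
5. **LFC.** `log2((k_A+1)/(S_A+1)) - log2((k_B+1)/(S_B+1))` — pseudocount-
   regularized normalized means, finite for one-sided zeros and exactly
   antisymmetric under cluster swap.
6. **Significance.** `p < 0.05` (strict) and `|LFC| ≥ 0.6` (inclusive). The
   raw p-value is used by default; the BH-adjusted column is always reported
   and selectable, since the upstream vendor tool reports adjusted values
   and the study's wording does not disambiguate.

At dispersion zero the exact test reduces to the binomial split test, which
the suite verifies against brute-force enumeration to 1e-12. Type-I error on
null NB simulations (2 000 genes, 100 spots per cluster, dispersion 0.1) is
checked to lie in [3.5%, 6.5%] at nominal 5%.

## Recording-quality metrics

The signal-quality algorithm is implemented exactly as the field computes
it for 16-channel arrays sampled near 48 kHz:

* **CAR.** The across-channel mean is subtracted at every sample. With
  independent per-channel sources this removes common-mode noise exactly
  and scales each channel's own spikes by `(n-1)/n` — an inherent property
  of the reference, visible as a few-percent downward bias in recovered
  SNR.
* **Spike band.** 500–6000 Hz Butterworth band-pass (order-4 prototype,
  8 poles), applied forward-backward for zero phase. The 8-pole cascade is
  what meets a 40 dB stop-band above 10 kHz; a 4-pole band-pass cannot.
* **Snippets.** Threshold at ±3.5 SD of the full filtered trace; at the
  first supra-threshold sample of an excursion the absolute minimum within
  half a window is located and a 2.4 ms window centred there is extracted;
  the scan resumes past the window end and a new window may never reach
  back into the previous one (greedy left-to-right overlap resolution).
  Samples outside all windows form the noise floor.
* **Channel inclusion.** A channel is kept when its noise-floor RMS lies
  within 0.3–2 times the array mean (inclusive bounds, single pass over all
  channels) — a damaged-site detector.
* **SNR** = mean snippet peak-to-peak over `6 × SD(noise floor)`.
  **MUA** = mean of supra-threshold positive deflections minus mean of
  sub-threshold negative deflections. **LFP** = `6 × SD` of the raw
  (pre-CAR) signal after a 60 Hz notch (2nd-order IIR, Q = 30) and a
  1–300 Hz 4th-order Butterworth band-pass, both zero-phase. Implant
  values average included channels with defined values.

Two numerical choices matter. First, an 8-pole 1–300 Hz band-pass at
48.8 kHz is unstable in double-precision direct form (its poles crowd
`z = 1`), so the LFP path decimates to ~1 kHz first — an FFT brick-wall
anti-alias followed by integer subsampling — and runs the prescribed filters
at the decimated rate, which leaves the 1–300 Hz band untouched. Second,
zero-phase filtering of finite traces ordinarily rings at the data edges;
the high-Q notch makes this visible. Both LFP filters therefore run with
matched initial conditions (steady-state state vectors) on a signal extended
at both ends by autoregressive (Burg) prediction, which continues narrow-band
content smoothly across the boundary; a 100 µV 60 Hz tone leaves a residual
amplitude below 0.1 µV.

## The synthetic-data module

The generator produces data with the statistical structure the analysis
assumes, not biological realism beyond it:

* **Spot lattice.** Rectangular grid at 100 µm pitch. Counts are negative
  binomial, `NB(mean = depth_j · p_g(d_j), dispersion φ)`, with radial
  proportions `p_g(d) ∝ baseline · (1 + (amplitude-1)·e^{-d/decay})`
  renormalized per spot. Defaults: mean depth 50 000 UMI per spot with
  lognormal spread (CV 0.4) — totals in real capture areas vary severalfold,
  and without that spread the housekeeping-linearity QC would have nothing
  to detect — and dispersion 0.02, the modest overdispersion of deep spots.
  The default panel carries *Gfap* (8-fold up at the tract, 150 µm decay),
  *Snap25* (down-regulated), a few inflammation markers, the housekeeping
  pair, and neutral filler with a long-tailed abundance distribution.
* **Recordings.** Spikes at Poisson times (default 20 Hz, the scale of
  aggregate multi-unit events on a cortical site) using a ~0.8 ms biphasic
  template — a 2 kHz Gabor, chosen so its energy sits mid-band and its
  peak-to-peak amplitude is invariant under the spike band-pass. The noise
  floor is spike-band-shaped Gaussian noise rescaled exactly to
  `noise_sd_uv`, so the planted value is the quantity the SNR denominator
  estimates; the LFP component is brick-wall 5–150 Hz Gaussian with exact
  SD (cortical LFP power concentrates there, and a component occupying the
  full 1–300 Hz band would lose ~3% SD at the band edges under the
  prescribed zero-phase response, making exact 6σ recovery impossible by
  construction). Optional 60 Hz line and common-mode components exercise
  the notch and CAR.
* **IHC.** Neuron centroids from an inhomogeneous Poisson process with
  density `far · (1 - e^{-d/r})` (suppression near the tract) and a GFAP
  intensity field `baseline + peak·e^{-d/decay}` plus pixel noise.
* **Cohorts.** Implanted samples (default 9, three per timepoint) carry
  per-animal lognormal scatter of marker effect amplitudes, a per-timepoint
  scaling of the tract effect (1, 0.7, 0.4 at 24 h, 1 week, 6 weeks —
  differential expression resolves over the time course), and metrics
  generated from the planted linear model
  `metric = α + Σ β_g·x_g + ε`, where `x_g` is the analytic expected
  electrode-site MNA of gene `g` for that sample. Naive samples have no
  tract effect and no recording metrics. An optional shared latent factor
  makes chosen markers co-vary, modelling a common underlying
  foreign-body-response severity.

What passing tests on this generator do *not* show: robustness to spatial
artifacts beyond a supplied mask, to segmentation or registration error, to
non-exponential radial profiles, or to count models with gene-specific
mean–variance relationships. The generator is a contract for the pipeline's
statistics, not a tissue simulator.

## The biomarker screen

Significant DE gene lists from the per-timepoint comparisons are
consolidated by set union; a gene significant at several timepoints is
represented by its largest-magnitude LFC with sign preserved (taking the
signed maximum would discard strong down-regulation). For each consolidated
gene, its electrode-site MNA across implanted samples is regressed on each
metric (MUA, LFP, SNR, GFAP intensity, neuronal density); the R² and the
non-adjusted F-test p-value are reported. Samples are pooled across
timepoints, matching a design with too few animals per timepoint for
stratified fits.

For gene sets, each gene is z-scored across samples (so no gene dominates by
scale), PCA is run, and the metric is regressed on the per-sample PC1 score
— the only per-sample quantity available for regression; gene loadings are
diagnostics. For a singleton set this reduces exactly to the single-gene
regression, an identity the tests assert to 1e-9. Enumerating "every
possible combination" of hundreds of genes is intractable
(2^645 subsets), so enumeration runs over a pool of the top genes by |LFC|
(default 10) at sizes 2–5 under a hard cap with a warning.

Candidates are selected per metric by min–max normalizing |LFC| and R² to
[0, 1] and scoring each gene by the *minimum* of the two — a conservative
"both must be high" rule; ties break by R², then name, and the
Pareto-undominated front is also flagged. `k` is restricted to 4–7. The
recovery property this must satisfy — three planted true biomarkers found
among fifty decoys that are high on exactly one axis in at least 90% of
cohorts — is checked by `biomarker_recovery_experiment()`, which builds the
decoy structure directly: high-LFC decoys have no link to the metric, and
high-coefficient decoys have a weak tract effect, hence little
between-animal expression spread and little predictive power.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit seed and is bitwise reproducible;
`run_pipeline()` writes all stage outputs as TSV/JSON and two runs from the
same configuration produce byte-identical files. The validation suite uses
deliberately compact problem sizes — lattices of 10–21 spots per side,
panels of 30–200 genes, 50–100 Monte-Carlo replicates, five-second
recordings — chosen so the full statistical contracts (calibration bands,
power, formula recovery) are still measurable; all sizes scale up through
the same configuration objects.

## Known limitations

* The DE test stands in for a vendor tool's unpublished internals: it is the
  same model family (shrunken-dispersion NB exact test), not a byte-level
  clone, so gene lists on real data will differ in detail.
* With eight samples, single-gene R² values are noisy and the null F-test
  only controls the error rate on average; the screen is a hypothesis
  generator, not an inference procedure, and no multiplicity correction is
  applied to the screen's p-values by design.
* The pipeline accepts pre-registered inputs (spot positions, tract
  annotation, artifact mask, IHC point sets and intensity fields); no image
  processing is performed.
* Whether excluded channels should also be omitted from the inclusion mean
  itself (iterative exclusion) is left as the single-pass variant; LFP
  averages are restricted to included channels for consistency with SNR and
  MUA.
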