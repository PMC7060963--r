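---
title: "Models and methods behind cardiotransit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiotransit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotransit)
```

This vignette is the package's own account of its models: what is
simulated, what is estimated, which knobs matter, and where the design
was genuinely open.

## 1. The calcium-imaging arm

### The transient waveform

A paced cell is modelled per stimulation epoch (epoch length
$1/f_{\mathrm{pace}}$, default $f_{\mathrm{pace}} = 0.25$ Hz) by three
parameters that are *defined through the analyzer*: peak amplitude $A$
(F/F0), rise time $t_r$ (15%-height crossing to peak, ms), and decay-50
$t_{50}$ (peak to half-height, ms). The waveform is

* a resting baseline at $F_0$;
* a raised-cosine upstroke
  $1 + (A-1)\,\tfrac12\bigl(1-\cos(\pi t/T_{up})\bigr)$ whose duration
  $T_{up} = t_r / \bigl(1 - \arccos(0.7)/\pi\bigr)$ is chosen so that the
  interval from the 15%-height crossing to the peak equals $t_r$
  *exactly*;
* a monoexponential decay with $\tau = t_{50}/\ln 2$, so the
  peak-to-half-height interval equals $t_{50}$ exactly.

Two refinements keep the definitions exact *after* smoothing:

* **C¹ peak cap.** A cosine-to-exponential joint has a derivative jump
  at the peak, and the 21-point smoother then shifts the peak by about
  two samples — enough to violate the package's own one-line-period
  recovery bound. A short cubic cap (3% of $\tau$) matches value and
  slope on both sides, making the peak C¹. It only touches the top ~1%
  of the decay, far above the half-height crossing.
* **Return to baseline.** A pure exponential never rests, and a trace
  that never rests biases any resting-level estimator. Once the decay
  reaches a small fraction of the height (5% where the epoch allows,
  adaptively more when rise and decay nearly fill the epoch), a smooth
  100-ms ramp returns the trace to baseline, guaranteeing a genuine
  diastolic segment in every epoch. The cut never rises above 43% of
  the height, so the half-decay crossing always lies on the pure
  exponential.

Parameters must satisfy $t_r + 2\,t_{50} < 1000/f_{\mathrm{pace}}$ (ms)
— the transient has to fit its epoch — and $A \ge 1$, with $A = 1$
encoding a cell without a transient.

### The line-scan noise model

`gen_linescan()` renders the waveform as a lines × pixels array.
Each pixel intensity is an independent Poisson draw with expectation
$g \cdot w(t_{\mathrm{line}}) \cdot s(\mathrm{pixel}) \cdot
e^{-\beta t}$: photon gain $g$ (default 0.5 expected photons per
intensity unit, i.e. ~50 photons/pixel at the default resting intensity
of 100 a.u. — a realistic confocal photon budget), a flat (default) or
Gaussian spatial profile, and optional monoexponential bleaching
(default off). With `noise = FALSE` the expectation itself is returned,
giving the exact infinite-photon limit used by the recovery tests.

### Populations and hierarchy

A `population_preset` holds group-level means plus two variance
components: cells scatter around their batch's mean with SD
$\mathrm{CV} \times \mathrm{mean}$ (default CV = 0.2) and each
differentiation batch contributes an additive Normal shift with SD 5%
of the metric mean (3 batches by default). Neither magnitude is
reported for the real populations — figure bars show mean ± SD only —
so these are stated stand-ins chosen to give realistic cell-to-cell
spread; they are deliberately held fixed everywhere. Draws violating
the parameter invariants are redrawn (at most 100 times) and cells are
assigned to batches as evenly as possible (181 cells → 61/60/60).

The four calibrated presets pin the group means to the reported
population means:

| group | amplitude (F/F0) | rise (ms) | decay-50 (ms) | n cells |
|---|---|---|---|---|
| WT | 2.8 | 169.5 | 603.5 | 181 |
| KO | 3.5 | 199.0 | 460.8 | 183 |
| WT + helothermine | 2.5 | 207.1 | 731.9 | 180 |
| KO + helothermine | 2.8 | 170.0 | 650.2 | 180 |

Treated-group cell counts are not reported and default to 180.

With 3 batches at 5% between-batch SD, the sampling SE of a group grand
mean is ≈ 3% of the mean (batch term dominates), so recovering a
printed mean within ±5% from one simulated population is expected but
not certain — a point to keep in mind when reading single-seed results.

### The measurement chain

`analyze_recording()` runs extract → smooth → baseline → normalize →
segment → measure → summarize:

* **Trace extraction** is the mean over the pixel axis per line.
* **Smoothing** is Savitzky–Golay, polynomial order 6 over a 21-point
  window ("6th order, 10 neighbors"), the standard realization of local
  polynomial smoothing; edges use the nearest full window's polynomial.
  Alternative edge rules (truncation, reflection) would change at most
  10 samples at each end and none of the metrics.
* **Baseline** is the median of all samples at or below the trace's
  20th percentile. The upstream acquisition software's "automatic
  recognition" of the resting level is proprietary; this estimator is a
  stated stand-in, robust because a 0.25-Hz-paced transient occupies a
  small duty cycle. It requires ≥ 100 samples and rejects an all-zero
  trace.
* **Normalization** divides by the detected F0 (amplitudes are F/F0);
  whether the original analysis normalized before or after smoothing is
  unstated — the pipeline fixes extract → smooth → baseline →
  normalize, and measures on the smoothed signal.
* **Segmentation** cuts contiguous windows of one pacing period
  starting at the stimulus offset; a trailing partial epoch is dropped
  (18.9 s at 0.25 Hz → 4 epochs, matching the 4 recordings averaged per
  cell).
* **Measurement** takes the epoch maximum (earliest index on ties) as
  the peak; onset is the last upward crossing of baseline + 0.15 ×
  height before the peak and decay-50 the first descent below
  baseline + 0.5 × height after it, both refined by linear
  interpolation between samples (the line period is 0.95 ms —
  interpolation removes the quantization bias). Epochs whose peak does
  not exceed the baseline by 10% of the baseline (configurable), or
  that never reach half-decay, are excluded and counted; a cell
  survives if at least one epoch does. Exclusion counts always appear
  in the run manifest.

Noiseless end-to-end recovery over a grid of amplitudes 1.5–5, rises
80–400 ms and decays 200–900 ms is within one line period for the time
metrics and 1% for amplitude (test-pinned); what the noisy tests then
add is photon noise, never model mismatch — real recordings, with
motion, dye saturation, or irregular spontaneous activity, are harder
than anything the generator produces, so passing tests bound the
pipeline's correctness, not real-data difficulty.

### Group statistics

`students_t()` is the classical pooled-variance two-tailed test
(df = $n_A + n_B - 2$) — pooled rather than Welch because that is the
named method being mirrored; tests run on per-cell values pooled across
batches (the real cell-level n's are reported that way), with batch
means available via the ANOVA. `random_effects_anova()` estimates
Model II variance components by expected mean squares:
$\hat\sigma^2_w = MS_w$,
$\hat\sigma^2_b = \max\bigl(0, (MS_b - MS_w)/n_0\bigr)$ with the
standard unbalanced-design $n_0$, and $F = MS_b/MS_w$. α = 0.05
throughout; no multiplicity correction across the three metrics (none
is applied in the mirrored analysis — noted, not endorsed). The rescue
rule per metric: toxin effect present in WT (WT+HELHO vs WT
significant) *and* treated KO indistinguishable from WT (KO+HELHO vs WT
not significant). `compute_ddct()` implements relative qPCR
quantification, fold = $2^{-\Delta\Delta C_t}$ against averaged
reference genes.

## 2. The transcriptomics arm

### Count model and generator

Counts are negative binomial, $\mathrm{Var} = \mu + \alpha\mu^2$, with
$\mu_{gs} = sf_s\,\mu_{0g}\,2^{L_{g,\mathrm{stage}(s)}}$: per-sample
library-size factors drawn uniformly from [0.7, 1.4], per-gene baseline
means (log-normal, median 150, unless fixed), dispersion default 0.05,
and planted per-stage log2 effects $L$. $\alpha = 0$ gives Poisson
draws. Designs follow the study: human NF (n = 4) vs CH (n = 5) vs mHF
(n = 5); mouse sham (n = 4) vs 1wTAC (n = 4) vs 8wTAC (n = 5) — the
sham size is not printed ("n = 4–5/group") and is set to 4.

The default concordance preset simulates 20 000 1:1 ortholog pairs with
25 planted concordant genes on a null background. The first planted
gene carries the profile of the headline candidate — human log2FC 1.6
(CH) and 2.6 (mHF), mouse 1.5 and 2.3 — and the rest are progressive
(late stage one log2 unit above the early stage) with magnitudes
cycling 1.8–2.4, alternating sign, mouse at 92% of the human magnitude;
planted baseline means are 300. These choices make the planted set
detectable by design — the preset tests the pipeline's recovery, not
the biological effect-size distribution.

### The DE chain

* **Size factors** are median-of-ratios: per sample, the exponential of
  the median log ratio of counts to the per-gene geometric mean across
  samples, over genes expressed everywhere. This matches the
  conventional reference implementation to floating-point accuracy
  (test-pinned against `DESeq2::estimateSizeFactorsForMatrix`).
* **Fold changes** are ratios of mean normalized counts with a
  pseudocount of 1 in numerator and denominator (the source analysis is
  silent; the pseudocount keeps log2FC finite).
* **Dispersion** is estimated per gene by method of moments: summed
  squared residuals of normalized counts around group means are equated
  with their NB expectation
  $\sum_s (1 - 1/n_{g(s)})(\mu_g/sf_s + \alpha\mu_g^2)$. With only
  ~7 residual degrees of freedom the raw estimate is far too noisy to
  plug into a likelihood-ratio test: genes whose dispersion is
  underestimated by chance get inflated statistics (null p-values
  measurably non-uniform) while overestimation silently costs power.
  A purely per-gene estimator cannot have both properties at this
  sample size, so the estimator shrinks each raw estimate toward the
  cross-gene median with weights $d : d_0$ (residual df against a prior
  df of 10) — the standard moderation idea used throughout RNA-seq
  tooling, in its simplest form. `prior_df = 0` restores the
  unmoderated estimator.
* **Testing** is a per-gene likelihood-ratio test at fixed dispersion:
  NB means fitted by Newton iteration (vectorized across genes, with
  size-factor offsets) under the null (one mean) and alternative (one
  mean per group), $2\Delta\ell$ referred to $\chi^2_1$. Genes with all
  zero counts across the contrast get p = 1 and are dropped from
  tables (counted in the log). This is a deliberately self-contained
  statistical core — it matches the full DESeq2 machinery (dispersion
  trend, Cook's filtering, LFC shrinkage) qualitatively, not
  numerically.
* **FDR** is Benjamini–Hochberg (`stats::p.adjust`), and the DEG filter
  is |log2FC| > 1 with q < 0.05 (the in-vitro variant 0.5/0.05 is a
  parameter, not a different code path).

### Concordance

Per species, each gene gets a per-stage call — up if log2FC > 1 and
q < 0.05, down symmetrically, else ns — and profiles join across the
1:1 ortholog map (non-1:1 and duplicated entries dropped and counted).
The conserved set keeps pairs whose human and mouse patterns are
identical and not (ns, ns); the published filtering lives in
unavailable supplementary methods, so this reconstruction is exposed as
configurable (`require_stages = "pattern"` default; `"all"` demands
significance at both stages). The heatmap matrix holds the four
contrasts' log2FCs, ordered by profile class then mean |log2FC|.

Under a pure null this filter is extremely stringent: a false
conserved pair needs coincident significance, magnitude and direction
in four contrasts; the 20-seed null simulation averages below one pair
at 20 000 genes.

## 3. Sequence utilities

Exon models carry coding lengths only (no genome coordinates): skipping
exons removes the summed coding length, a multiple of 3 is an in-frame
deletion of nt/3 amino acids, anything else flags a frameshift at codon
⌈preceding nt/3⌉ + 1. The packaged fixture encodes the edited CRISPLD1
transcript; only the combined 303-nt loss of exons 6–8 is documented,
so the per-exon split (117/96/90) is synthetic and labelled as such.

The aligner is textbook Needleman–Wunsch with linear gaps and a
deterministic traceback tie-break (diagonal > up > left), configurable
match/mismatch or substitution-matrix scoring; windowed identity counts
matching columns among those whose query residue lies in a 1-based
inclusive window, rounded to the nearest percent. Reproducing published
identity percentages for specific protein pairs requires the exact
database sequences and a local aligner, so those numbers are not
targets here; the window arithmetic is.

## 4. Numerical choices, sizes, limitations

* Line period 1/1057.7 s; times held in seconds internally, reported in
  ms. Crossing times linearly interpolated; peak ties take the earliest
  index; dispersion floored at $10^{-8}$; NB mean fits run ≤ 50 damped
  Newton steps in log space.
* All generators are deterministic given a seed; population and
  pipeline runs derive per-cell/per-group sub-seeds so any unit can be
  regenerated in isolation. Manifests record parameters, seeds and
  exclusion counts sufficient to re-run bit-identically.
* Test and acceptance problem sizes are the package's chosen working
  points: full-scale populations (181/183/180/180 cells at 20 000 × 512)
  for the headline recovery run, 2 000–3 000 genes for distributional
  properties, 20 000 ortholog pairs for concordance; the property suite
  uses scaled-down variants of the same generators.
* Known limitations: no motion artifacts, ratiometric dyes, or
  spontaneous (unpaced) activity in the imaging simulator; no dye
  saturation or background subtraction in the trace pipeline; the DE
  engine deliberately omits dispersion trends and LFC shrinkage;
  published dataset-level counts (total DEG numbers, pathway
  percentages) depend on the real data and are out of scope.
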