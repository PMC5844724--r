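---
title: "First-order MRI texture analysis for rectal-cancer treatment response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order MRI texture analysis for rectal-cancer treatment response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Locally advanced rectal cancer is treated with neoadjuvant chemoradiotherapy
(nCRT) followed by surgery. A quarter or so of patients show a pathological
complete response (pCR, ypT0N0) in the resected specimen; identifying them
before or early during treatment would open the door to organ-preserving
strategies. `rectexture` implements a texture-analysis workflow for this
question: first-order (histogram) features extracted from a manually drawn
tumor region of interest (ROI) on the single largest cross-section of the
oblique-axial T2-weighted MRI, measured before treatment ("pre") and at the
third week of chemoradiotherapy ("early"), read independently by two raters.

The analysis chain is: per-image feature extraction, two-rater agreement
(ICC), rater averaging, paired pre-vs-early comparisons (Wilcoxon
signed-rank), responder-vs-nonresponder comparisons (Mann-Whitney) under two
pathological reference standards (tumor regression grade TRG 1-2, and pCR),
and response prediction by ROC analysis of single features and of a
backward-elimination logistic combination.

Because no patient images are distributed with studies of this kind, the
package ships a synthetic phantom cohort generator whose defaults emulate a
59-patient study (30 TRG 1-2 / 29 TRG 3-5; 15 pCR / 44 non-pCR), so that
every stage can be exercised, tested and calibrated end to end.

## The seven features

Let $X(i)$, $i = 1 \ldots N$ be the raw intensities of the $N$ ROI pixels,
and let $P(i)$, $i = 1 \ldots k$ be the probabilities of a $k$-bin
equal-width discretization of those intensities spanning
$[\min X, \max X]$ (`n_bins`, default 32, recorded per row).

* mean $= \frac{1}{N}\sum_i X(i)$ and
  SD $= \left(\frac{1}{N-1}\sum_i (X(i)-\bar X)^2\right)^{1/2}$ — raw
  intensities, sample denominator for the SD.
* skewness $= m_3 / m_2^{3/2}$ and kurtosis $= m_4 / m_2^2$ with population
  central moments $m_j = \frac{1}{N}\sum_i (X(i)-\bar X)^j$. Kurtosis is
  non-excess: a Gaussian histogram gives 3. The mixed denominator
  conventions (sample for SD, population for the higher moments) are kept
  deliberately; they are the conventions of the reporting tradition this
  pipeline follows.
* uniformity $= \sum_i P(i)^2$, in $(0, 1]$, maximal when all mass is in
  one bin.
* entropy $= -\sum_i P(i)\log_2 P(i)$ in bits, in $[0, \log_2 k]$, with
  $0 \log 0 := 0$.
* energy $= \frac{1}{N}\sum_i \tilde X(i)^2$ where
  $\tilde X = (X - \min X)/(\max X - \min X)$: the mean squared
  min-max-normalized intensity, bounded in $[0, 1]$ and large when most
  pixels sit near the ROI maximum.

Two definitional switches exist for auditability against other software:
`uniformity_variant = "weighted"` computes $\sum_i i \cdot P(i)^2$ (an
index-weighted variant that can exceed 1), and
`energy_variant = "probability"` computes $\sum_i P(i)^2$ on the binned
probabilities. The defaults are the bounded, dimensionless forms above,
which are the only ones consistent with values in $(0, 1]$ reported for
these features in the clinical literature.

Skewness and kurtosis are computed on the *raw* (undiscretized)
intensities: binning first would discard information, and the raw
definition is what makes the Gaussian-limit sanity check (skewness 0,
kurtosis 3) meaningful.

Degenerate inputs are defined, not errors: a constant ROI puts all mass in
one bin (uniformity 1, entropy 0), has SD 0, undefined skewness/kurtosis
(returned as `NA` with a warning), and energy 1 (every pixel sits at the
single, maximal level).

## The synthetic cohort generator

A phantom is a smoothed Gaussian random field (default correlation length 2
px) whose in-ROI pixels are rank-transformed onto the deterministic
quantile grid of a target marginal distribution: the pixel of rank $r$ of
$N$ receives $Q((r-0.5)/N)$. Because first-order features ignore spatial
arrangement, this histogram matching controls the extracted features
essentially exactly (entropy of a uniform 32-level target is recovered
within 0.02 bits at $10^4$ ROI pixels) while the smoothing keeps images
visually coherent. The default ROI is a 25 x 18 px-semi-axis ellipse in a
64 x 64 image (about 1400 pixels, a plausible large rectal tumor
cross-section at small-field-of-view resolution); all dimensions are
configurable.

Target marginals are piecewise-uniform densities. The cohort defaults use a
peak-plus-background family: a dominant narrow component with mass `p_dom`
at relative position `dom_pos` over a uniform background. `p_dom` moves
uniformity, entropy and kurtosis together (concentration), `dom_pos` moves
energy (mass near the ROI maximum).

Key design choice: each patient's marginal is affine-standardized to a mean
and SD drawn *independently of response group* (mean ~ N(235, 45), baseline
SD ~ N(44, 8), in arbitrary T2 signal units). Uniformity, entropy, energy,
skewness and kurtosis are affine-invariant, so this cleanly decouples the
moment features from the shape features: group signal lives purely in
histogram shape, and the mean feature is a true negative control. A small
scan-level mean wobble (SD 6) is drawn per timepoint so that paired tests
on the mean face a genuine null rather than a degenerate zero-difference
one.

The group structure, in the directions reported for this clinical setting:

* complete responders (pCR), before treatment: higher `p_dom` (0.90 vs
  0.78) and higher `dom_pos` (0.75 vs 0.60) than nonresponders — so higher
  pre-uniformity and pre-energy, lower pre-entropy;
* TRG 1-2 responders without pCR sit between the extremes via a latent
  response score (1 / 0.45 / 0 with SD 0.18);
* the early scan relative to baseline: SD scaled up by 1.20, peak mass
  down 0.10 and peak width up 2.5-fold — so SD rises while kurtosis and
  uniformity fall, the paired-comparison signature.

The between-patient spreads (`p_dom_sd` 0.075, `dom_pos_sd` 0.12) were
calibrated once, by simulation at the default cohort size, so that the
three pretreatment histogram features separate pCR from non-pCR
significantly (Mann-Whitney, $\alpha = 0.05$) in roughly 90% of seeds —
clearly detectable but not trivially so, as in a modest single-center
cohort. `effect_scale = 0` collapses all groups onto one distribution and
is the generator's null mode, under which downstream p-values are uniform.

The second rater's ROI is a boundary perturbation of the true ellipse: a
smooth random field modulates the signed distance to the boundary, so the
perturbed mask always lies between the `jitter`-eroded and -dilated masks
and contiguous boundary stretches move together, as a human tracing error
would. The default jitter of 1.5 px yields ICCs in the 0.8-1.0 range
(excellent agreement), with the moment features more robust than
skewness/kurtosis — the same ordering seen with human readers. Jitter 0
gives identical masks, hence ICC exactly 1.

What the phantoms do *not* model: MR acquisition physics (Rician noise,
bias fields, partial-volume effects), anatomy, and any spatial texture
structure. Passing tests on phantoms therefore demonstrate the statistical
machinery and the feature definitions, not clinical performance on real
scans; second-order (spatial) features would be entirely unconstrained by
this generator and are out of scope.

All randomness flows from the master seed through deterministic per-patient
sub-seeds; identical specs give bit-identical cohorts, images and reports.

## Statistical choices

**ICC.** Interobserver agreement uses the two-way random-effects,
absolute-agreement, single-measurement coefficient, ICC(A,1): raters are
interchangeable readers and systematic offsets should count against
agreement. The variant label travels with every result. The 95% CI is the
F-distribution construction with Satterthwaite degrees of freedom; its
coverage was verified by simulation at the study's size (59 subjects, two
raters): 0.95-0.96 across true ICCs of 0.6 and 0.9 when rater variance
takes a small (5%) share of the non-subject variance, the regime this
design emulates. Agreement bands (poor/fair/moderate/good/excellent) use
the conventional 0.20/0.40/0.60/0.80 thresholds, half-open on the left;
negative estimates are classified poor, with a warning.

**Rank tests.** Pre-vs-early uses the Wilcoxon signed-rank test with zero
differences dropped (the classical convention); the exact null distribution
is used for at most 25 untied nonzero differences, otherwise the
tie-corrected normal approximation with continuity correction. The
responder comparisons use the Mann-Whitney test, exact when the smaller
group has at most 8 untied observations. Both tests hold their size within
[0.04, 0.06] at $\alpha = 0.05$ at the study's sample sizes (verified by
simulation in the test suite). Group summaries are median (Q1-Q3) with
linear-interpolation quantiles. No multiplicity correction is applied by
default, mirroring single-center reporting practice across the 14
parameter-by-timepoint tests; `p_adjust = "holm"` is available.

**ROC.** The AUC is the empirical Mann-Whitney pair-counting estimate
(ties count 1/2), oriented so AUC >= 0.5 with the orientation reported as
the cutoff direction (`>` or `<=`). The optimal cutoff maximizes the
Youden index, with ties broken toward the smallest threshold; cutoffs are
observed score values, so reported sensitivity/specificity are exactly
attained on the data (self-consistency is tested). AUC confidence
intervals and the paired comparison of correlated AUCs use DeLong's
variance estimate and test (via pROC); the paired test was cross-checked
against a 2000-draw paired bootstrap.

**Feature combination.** Features enter the multivariable candidate set
when univariately significant at $\alpha$ (Mann-Whitney by default; a
univariate-logistic gate is available, since reporting conventions differ
on this point). Backward elimination removes the worst Wald p-value above
$\alpha$ until all retained features are significant; a likelihood-ratio
criterion is available behind a flag. Perfect separation is detected and
reported as a warning naming the most extreme coefficient. All reported
performance is apparent (in-sample), labeled as such — there is no
train/test split, matching the design being emulated; with 7 candidate
features and 59 patients, apparent AUCs are optimistic and external
validity is explicitly out of scope.

## Problem sizes and tolerances

The test suite validates feature extraction against an independent
naive-loop implementation to $10^{-10}$ on random masked images including
tied intensities; exact-mode p-values against full enumeration
($2^n$ sign assignments, $\binom{n_1+n_2}{n_1}$ rank arrangements); AUC
against pair enumeration; and the pipeline's directional findings across
100 default cohorts. Simulation sizes (2000 replicates for test size, 2000
for ICC coverage, 100 seeds for the study emulation) were chosen so
Monte-Carlo noise is small against each acceptance band while the whole
suite stays comfortably fast on one CPU.

## Known limitations

* Single-slice, pixel-aligned boolean masks only; no sub-pixel or polygon
  ROIs, no 3D extraction (a 3D volume can be ingested by selecting a
  slice, including `"largest"` by mask area).
* First-order features only; spatial (GLCM/GLRLM, filtered) textures are
  out of scope.
* The effective bin count of commercial texture software is generally
  undocumented; results depend on `n_bins`, which is why it is recorded in
  every output row.
* Phantom realism is limited to the intensity marginal; see above.
* Exactly two raters; more general designs need a different agreement
  model.
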