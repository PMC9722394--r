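---
title: "Resting-state fNIRS connectivity screening: models and methods"
author: "nirsconn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state fNIRS connectivity screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsconn)
```

## Scope

`nirsconn` implements a complete two-group screening analysis for
resting-state functional near-infrared spectroscopy (fNIRS): from raw
dual-wavelength light intensities to motion-corrected hemoglobin time
series, Fisher-z functional connectivity at channel and region-of-interest
(ROI) level, mass-univariate edge statistics with false-discovery-rate
control, ROC-based feature screening, and repeated cross-validated linear
discriminant classification. The target application is the comparison of
amnestic mild-cognitive-impairment (aMCI) patients with healthy controls
(HC) on a 71-channel whole-head montage, but every stage is generic in the
montage and group labels.

Because clinical recordings of this kind are rarely shareable, the package
ships a calibrated synthetic cohort generator that reproduces the
statistical structure the analysis assumes. All tests and the bundled
acceptance study run on synthetic cohorts; what that does and does not
demonstrate is discussed at the end.

## The measurement model

A continuous-wave fNIRS channel records light intensity $I_\lambda(t)$ at
two wavelengths (730 and 850 nm here). Attenuation changes are expressed
as optical density relative to the channel's mean level,

$$\Delta OD_\lambda(t) = -\log_{10}\frac{I_\lambda(t)}{\bar I_\lambda},$$

and related to chromophore concentration changes by the modified
Beer-Lambert law,

$$\Delta OD_\lambda = \big(\varepsilon_{HbO}(\lambda)\,\Delta HbO +
\varepsilon_{HbR}(\lambda)\,\Delta HbR\big)\, \mathrm{DPF}\, L,$$

with molar extinction coefficients $\varepsilon$ (Gratzer/Prahl
compilation, bundled as a data file), differential pathlength factor
$\mathrm{DPF} = 6.0$ and source-detector separation $L = 3$ cm. Two
wavelengths give a $2\times 2$ linear system per time point, solved
exactly by `odToHb()`. Downstream analysis uses $\Delta HbO$ only, the
conventional choice for resting-state connectivity because of its higher
signal-to-noise ratio; $\Delta HbR$ is computed and retained.

## Preprocessing

`preprocess()` applies, in order:

1. **Channel quality control.** Per channel and wavelength,
   $\mathrm{SNR} = 20\log_{10}(\mathrm{mean}(d)/\mathrm{sd}(d))$ dB on the
   raw intensity $d$; a channel is excluded when either wavelength falls
   below 10 dB. The factor 20 (amplitude-ratio convention) is a package
   choice — the dB convention is configurable (`snrDbFactor`) — and makes
   realistic resting intensities land in the tens of dB. A subject is
   dropped entirely when more than 20% of channels fail
   (`subjectDropFrac`); otherwise failing channels are excluded pairwise
   from edge statistics.
2. **Motion-artifact detection** on optical density: a sliding window of
   `tMotion` = 0.5 s is flagged when its max-min excursion exceeds
   `SDThresh` = 20 times a robust SD (1.4826 x MAD) of the
   first-differenced series, or `AMPThresh` = 3 OD absolutely; flagged
   windows are dilated by `tMask` = 1 s per side and merged. The windowed
   max-min against a differenced-series reference is our concrete reading
   of the "moving standard deviation" family of detectors; both thresholds
   are exposed under their conventional names. Note the relative
   threshold presumes a sensor noise floor; on strictly noise-free
   signals the reference SD degenerates to the signal's own derivative.
3. **Smoothing-spline correction** (`splineCorrect()`): a cubic smoothing
   spline with parameter $p = 0.99$ is fitted to each artifact segment and
   subtracted, removing the artifact shape while keeping the residual
   fluctuation; the segment and all subsequent samples are then shifted so
   the series is level-continuous at both boundaries. We follow the csaps
   convention ($p=1$ interpolates, $p=0$ is a straight line) with the
   abscissa in sample units; `smooth.spline`'s internal rescaling of $x$
   to $[0,1]$ is compensated by dividing its roughness weight by
   $(n_{seg}-1)^3$. Segments shorter than four samples fall back to
   linear detrending.
4. **Zero-phase band-pass, 0.01-0.1 Hz**: forward-backward Butterworth
   filtering, implemented as a high-pass/low-pass cascade of order 3 each
   (a single narrow band-pass in transfer-function form is poorly
   conditioned at these normalized frequencies). The input is demeaned
   first so DC rejection is exact. This removes drift, Mayer waves at the
   band edge, respiration (~0.25 Hz) and cardiac pulsation (~1.1 Hz,
   aliased or not) by more than 20 dB while keeping the hemodynamic band
   within 1 dB. The zero-phase property matters because connectivity is a
   correlation at lag zero.
5. **Beer-Lambert inversion** as above.

Motion correction operates on optical density before conversion — the
standard domain for spline methods; every stage's diagnostics (QC table,
corrected segments) are retained in the result's metadata.

## Connectivity and group statistics

`channelFC()` computes Pearson correlations between all channel pairs over
the full recording and applies the variance-stabilizing Fisher transform
$z = \operatorname{atanh}(r)$, with $|r|$ clipped at $1 - 10^{-7}$ so
degenerate (duplicated) channels stay finite; 71 channels give
$71 \cdot 70/2 = 2485$ undirected edges. `roiFC()` first averages the HbO
series of each ROI's passing channels, then correlates the nine ROI means
(36 edges) — averaging before correlating, which follows the description's
word order and raises the effective SNR of regional signals. The
whole-brain summary is the mean z over all 2485 edges
(`wholeBrainMean()`), with missing edges excluded and counted.

`runEdgeStats()` performs, per edge, a pooled-variance two-sample t test
($df = n_1 + n_2 - 2$, i.e. 126 at 64 per group), Benjamini-Hochberg FDR
adjustment within the analysis level (2485 channel edges or 36 ROI edges),
and ROC analysis via the Mann-Whitney identity — the AUC is the fraction
of (HC, MCI) subject pairs with $z_{HC} > z_{MCI}$, so edges weakened in
patients give AUC > 0.5. The operating point maximizes Youden's $J$;
sensitivity is the fraction of patients below the threshold and
specificity the fraction of controls at or above it (the ROC convention
had to be fixed by us; it is reported alongside the numbers). The pooled
(equal-variance) t form is forced by the 126 degrees of freedom
convention; Welch is deliberately not the default. BH was chosen as the
field-standard FDR procedure.

## Classification

Edges surviving the screening rules — ROI edges with AUC > 0.65 (FDR <
0.05), channel edges with FDR-adjusted p < 0.01 — enter a two-class linear
discriminant analysis: $w = \Sigma^{-1}(\mu_{HC} - \mu_{MCI})$ with pooled
covariance, threshold at the projected-mean midpoint shifted by the log
prior ratio (priors from training fractions), and a $10^{-8}$ ridge if the
covariance is singular. `repeatedCV()` evaluates each feature set with
stratified 5-fold cross-validation repeated 10 times; the per-repeat
accuracy pools correct/total over the concatenated validation folds (the
alternative fold-mean aggregation is available). Feature selection is, by
design, performed once on the full cohort before cross-validation — this
reproduces the screening procedure being modeled and therefore inherits
its selection optimism; a leakage-free nested variant is a deliberate
non-goal here. Per-repeat fold seeds derive deterministically from one
master seed.

For a single standardized edge with group difference $d$, the Bayes
accuracy of the pooled-Gaussian model is $\Phi(d/2)$; this closed form is
used as an oracle in the test suite.

## The synthetic cohort generator

`simulateSubject()` builds one recording as follows:

1. A subject-level $9\times 9$ inter-ROI correlation matrix is drawn
   around the group's latent Fisher-z coupling matrix: every edge receives
   a shared global jitter $g_i \sim N(0, 0.212)$ plus independent edge
   jitter $N(0, 0.02)$; the result is mapped through $\tanh$ and repaired
   to the nearest correlation matrix if needed (eigenvalue clipping).
2. Band-limited (0.01-0.1 Hz) unit-variance Gaussian ROI signals with that
   correlation are synthesized from Gaussian weights on the in-band
   Fourier modes of the recording grid (flat spectrum in band).
3. Channel HbO mixes the parent-ROI signal with independent band-limited
   noise. The baseline mix (0.85) implies a within-ROI channel
   correlation of about 0.97; the subject's global jitter also moves this
   within-ROI coupling on the z scale, with gain 2 relative to the
   long-range edges, so short- and long-range coupling co-vary as one
   continuum across subjects. The gain value makes the ratio of
   whole-brain to single-edge between-subject SDs match the reference
   moments (about 0.21 vs 0.24); with a fixed mix that ratio is
   structurally too small. Channel fluctuations are scaled to 0.5 uM.
4. HbR is $-0.3 \times$ HbO plus independent band-limited noise (0.1 uM) —
   simulated only to make the two-wavelength inversion well-posed.
5. Forward Beer-Lambert with the same extinction table, DPF and geometry
   as the inverse step; physiological nuisance sinusoids (cardiac 1.1 Hz,
   respiratory 0.25 Hz, Mayer 0.095 Hz; amplitudes 0.005/0.002/0.0005 OD)
   with per-channel random phases and a few percent subject-level
   frequency jitter; per-channel linear drift (up to 0.012 OD); intensity
   $I = g\,10^{-\Delta OD}$ with per-channel gains and 0.6% sensor noise.
   These nuisance defaults are literature-conventional orders of
   magnitude, chosen so that in-band contamination attenuates connectivity
   by well under 0.02 in z (the out-of-band components are removed by the
   filter anyway); they put typical channel SNR in the 25-40 dB range.
6. Motion events at 0.3/min (half spikes of 0.2-0.4 s, half persistent
   baseline steps), with per-channel amplitudes straddling the detection
   threshold, are added to both wavelengths and logged as ground truth.

`simulateCohort()`/`processCohort()` derive per-subject seeds
deterministically from one master seed; identical specs reproduce
bit-identical cohorts.

### Calibration of the defaults

`defaultCohortSpec()` must reproduce, after the full pipeline, the
reference group moments of the study the generator emulates: whole-brain
mean z of 0.85 (HC) vs 0.74 (MCI), and six weakened long-range ROI edges
(RPF-RO 0.83/0.69, RPF-LIP 0.78/0.63, LPF-LO 0.78/0.63, RPF-P 0.69/0.54,
LPF-P 0.64/0.49, RPF-LO 0.77/0.60 in z). Because mixing, nuisance, sensor
noise and filtering each attenuate correlations slightly — and the
attenuation is strongest for the near-unity within-ROI pairs — the latent
couplings cannot be read off these targets analytically. They were
calibrated empirically: starting from the analytic inverse of the mixing
attenuation, replicate cohorts were run through the complete pipeline,
measured group moments were compared with the targets, and additive
latent-z corrections were applied until all means agreed to within
sampling error (&lt; 0.005); the resulting constants are frozen in the
package. The measured between-subject SDs (0.217 whole-brain, 0.231
edge-level) then imply a whole-brain t near 2.9, an RPF-LO t near 4.0,
an RPF-LO AUC near 0.69 and a single-edge LDA accuracy near 64% at the
reference sample size of 64 per group.

### What the generator does not emulate

Synthetic cohorts share the analysis chain's own assumptions: Gaussian
band-limited signals, linear mixing, stationary coupling, a single global
heterogeneity factor, additive sinusoidal nuisance. Real recordings have
non-Gaussian and non-stationary hemodynamics, spatially structured
superficial (scalp) physiology that can inflate short-range correlations,
heterogeneous optode coupling, and motion artifacts far more varied than
spike-plus-step events. Passing tests therefore demonstrate that the
pipeline implements its stated statistics correctly and recovers known
structure under its model — not that the screening accuracy would transfer
to clinical data.

## Numerical and design choices

- **Edge cases.** Perfectly correlated pairs are clipped at
  $|r| = 1-10^{-7}$ ($z \approx 8.38$); zero-variance channels yield
  missing edges; missing edges propagate with reported denominators
  (2485 minus the failed channel's pairs).
- **Determinism.** All randomness flows from explicit integer seeds
  through deterministic per-subject/per-repeat derivations; reruns are
  byte-identical, which the test suite asserts on the emitted tables.
- **Filter edges.** The zero-phase high-pass at 0.01 Hz has an O(100 s)
  transient at the recording boundaries (handled with the conventional
  zero-padded forward-backward pass); comparisons against ground truth in
  the tests trim these edges.
- **Performance.** The inner kernels (IIR filtering, rolling range, OD
  conversion, Beer-Lambert inversion, the intensity forward model) are
  implemented in C++; band-limited noise is composed on cached Fourier
  bases. A 128-subject cohort (71 channels x 11400 samples) runs end to
  end in about two minutes on one core. The replicate studies in the test
  suite and the acceptance script use ten such cohorts — the scale at
  which the calibrated moments are resolved well inside their tolerances —
  while unit tests use 60-300 s recordings and 2-12 subjects.
- **Degenerate inputs.** Non-positive intensities abort with the offending
  channel/sample; simulated intensities are clipped positive with a
  warning in the (practically unreachable) event sensor noise exceeds the
  signal; an empty cohort or a cohort whose subjects all fail QC aborts
  the pipeline with the failing stage named.

## Limitations

Beyond the generator's idealizations: the SNR dB convention and the exact
semantics of the motion-detection thresholds are package choices among
several used in practice (both configurable); feature selection precedes
cross-validation by design, so reported accuracies estimate the modeled
procedure, not generalization error; and no wavelet/PCA motion correction,
short-separation regression, dynamic connectivity or graph metrics are
provided — they are outside this package's scope.
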