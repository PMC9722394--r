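# nirsconn

Resting-state functional connectivity screening for multichannel
functional near-infrared spectroscopy (fNIRS), aimed at two-group clinical
comparisons such as amnestic mild cognitive impairment (aMCI) versus
healthy controls (HC). The package is written for neuroimaging
methodologists and clinical researchers who need the complete chain from
raw dual-wavelength light intensity to classification-ready connectivity
biomarkers, with every stage testable offline.

## What it computes

Raw intensities $I_\lambda(t)$ at 730/850 nm are converted to optical
density, screened by channel SNR (exclusion below 10 dB), corrected for
motion artifacts (moving-window detection with `SDThresh` = 20,
`AMPThresh` = 3, `tMotion` = 0.5 s, `tMask` = 1 s; smoothing-spline
subtraction with p = 0.99), band-passed to 0.01-0.1 Hz with a zero-phase
Butterworth cascade, and inverted through the modified Beer-Lambert law

$$\Delta OD_\lambda = (\varepsilon_{HbO}(\lambda)\Delta HbO +
\varepsilon_{HbR}(\lambda)\Delta HbR)\cdot \mathrm{DPF}\cdot L,
\qquad \mathrm{DPF}=6.0 .$$

Functional connectivity is the Fisher-transformed Pearson correlation
$z = \operatorname{atanh}(r)$ of HbO time series, at channel level
(71 channels, 2485 undirected edges) and ROI level (nine regions, 36
edges, member series averaged before correlating). Group inference per
edge uses the pooled two-sample t ($df = n_1+n_2-2$), Benjamini-Hochberg
FDR within each level, and ROC analysis via the Mann-Whitney identity
with a Youden operating point. Screened edges (ROI AUC > 0.65; channel
FDR-adjusted p < 0.01) feed a pooled-covariance linear discriminant
classifier evaluated by stratified 5-fold cross-validation repeated 10
times.

A calibrated synthetic cohort generator (`defaultCohortSpec()`,
`simulateCohort()`) produces two-group cohorts — 64 subjects per group,
71 channels, 19 Hz, 600 s — whose processed group moments match the
reference study conditions (whole-brain mean z 0.85 vs 0.74; six weakened
long-range prefrontal-posterior edges, strongest at RPF-LO with 0.77 vs
0.60). See the methods vignette (`vignettes/nirsconn-methods.Rmd`) for
models, calibration and limitations.

## Worked example

```r
library(nirsconn)

run <- runPipeline(defaultCohortSpec(), outDir = "results/demo",
                   repeats = 10, writeMatrices = FALSE)
makeReport(run)
```

Output of this exact call (one calibrated 128-subject cohort, about two
minutes on one core):

```
Whole-brain mean connectivity (Fisher z):
  HC  0.80 +/- 0.21   MCI 0.71 +/- 0.22
  t(126) = 2.29, p = 0.0239
Top 6 ROI edges by AUC:
  RPF-LO  AUC 0.713  t(126) = 4.09  p_fdr 0.00276 **
  RT-RO  AUC 0.685  t(126) = 3.34  p_fdr 0.00696 **
  LPF-RIP  AUC 0.680  t(126) = 3.48  p_fdr 0.00696 **
  LO-RO  AUC 0.670  t(126) = 3.20  p_fdr 0.00696 **
  RT-LO  AUC 0.669  t(126) = 3.20  p_fdr 0.00696 **
  RPF-RIP  AUC 0.668  t(126) = 3.14  p_fdr 0.00696 **
Channel edges at FDR < 0.01: 0
Classification accuracy (10 repeats):
  RPF-LO               mean 68.44 +/- 0.75 %, max 69.53 %
  RT-RO                mean 65.00 +/- 0.96 %, max 66.41 %
  LPF-RIP              mean 67.19 +/- 0.97 %, max 69.53 %
  LO-RO                mean 60.70 +/- 0.64 %, max 61.72 %
  RT-LO                mean 63.75 +/- 1.12 %, max 65.62 %
  RPF-RIP              mean 63.83 +/- 0.53 %, max 64.84 %
  All above            mean 61.48 +/- 0.53 %, max 62.50 %
```

Reading it: the patient group shows globally weakened connectivity
(whole-brain z 0.71 vs 0.80; the group t fluctuates around its calibrated
expectation of ~2.9 from cohort to cohort). The RPF-LO edge — right
prefrontal to left occipital — tops the AUC ranking as calibrated, and a
single-edge linear discriminant reaches ~68% cross-validated accuracy on
this cohort, the scale expected for a standardized group difference of
~0.7 at 64 subjects per group ($\Phi(d/2)$). `results/demo/` holds the QC report,
long-format connectivity, per-edge statistics and the accuracy grid as
TSV, plus a JSON manifest with the config hash and seeds; identical
configs rerun byte-identically.

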