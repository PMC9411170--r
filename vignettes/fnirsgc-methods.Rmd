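---
title: "Methods: directed fNIRS networks by nonparametric spectral Granger causality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed fNIRS networks by nonparametric spectral Granger causality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsgc)
```

# The analysis in one paragraph

`fnirsgc` implements a complete brain--behavior pipeline for repeated-trial
fNIRS experiments. Raw two-wavelength optical intensities are converted to
region-level oxyhemoglobin (HbO2) series; directed functional connectivity
between five cortical regions (LPFC, RPFC, LPMC, RPMC, SMA) is estimated on
the first 54-s window of every trial by *nonparametric spectral Granger
causality* -- cross-spectral estimation, Wilson minimum-phase factorization,
Geweke frequency-domain decomposition, and averaging over the 0.01--0.07 Hz
neurovascular band -- yielding 20 directed edges per trial; trial-to-trial
variability is summarized as coefficients of variation (CoV); and a standard
inference chain (two-factor between-subject effect tests with partial
eta-squared, Benjamini--Hochberg FDR control, backward-elimination
regression, recursive path analysis) links connectivity and its variability
to task performance. Because real recordings of this kind are rarely shared,
the package includes a first-class synthetic-data generator with known
vector-autoregressive (VAR) ground truth, so every stage is validated by
parameter recovery.

# Generative model

## Ground-truth networks

Hemodynamics are modeled as a stationary VAR acting on a *coupling grid*
(default 2 Hz): for regions $x_t \in \mathbb{R}^R$,
$$x_t = \sum_{k=1}^{p} A_k\, x_{t-k} + \varepsilon_t,\qquad
  \varepsilon_t \sim \mathcal N(0, \Sigma),$$
with the companion-matrix spectral radius required to be below 1. Strong AR
self-couplings (0.8--0.9) put the half-power point of each region's spectrum
near 0.03 Hz, so power concentrates in the neurovascular band the analysis
reads out, while off-diagonal entries of $A_1$ are the directed couplings
the estimator must recover. The grid rate matters: a 54-s window holds 108
samples of a 2 Hz VAR, enough to detect direction reliably, whereas a much
slower grid (e.g. 0.2 Hz, ~11 samples per window) makes single-window
direction recovery information-theoretically hopeless regardless of the
estimator. The implied causal latency of one grid step (0.5 s) is within the
range of plausible inter-regional hemodynamic lags.

The series is linearly interpolated to the acquisition rate (default 25 Hz)
and white measurement noise (default 0.01 uM) is added. Interpolation is a
common per-channel linear filter, which leaves Granger causality unchanged
in the band; the broadband measurement noise gives the spectrum a floor that
keeps the factorization well conditioned. The result is
*power-concentrated*, not strictly band-limited, below ~0.1 Hz; the
preprocessing bandpass enforces the band for optics-level data.

For any ground-truth network the population band-averaged GC is computable
without data: the analytic spectral matrix is
$S(f) = H(f)\,\Sigma\,H(f)^* / f_s$ with
$H(f) = (I - \sum_k A_k e^{-2\pi i f k / f_s})^{-1}$; for a region pair the
2x2 marginal spectrum is Wilson-factorized and pushed through the Geweke
formula (`population_band_gc()`). For bivariate networks this reduces to a
closed form that a few lines of independent code can verify, which is how
the estimator is benchmarked.

## Study generator

`generate_study()` realizes a 2 (skill: expert/novice) x 2 (simulator:
physical/VR) design with 7 + 6 subjects and 5 trials per subject and
condition, the layout of the motor-skill training experiments this pipeline
targets. Group/condition structure enters as additive coupling offsets
(default +-0.1) on a sparse set of fronto-motor edges; each trial jitters
the directed couplings multiplicatively (log-normal, sd 0.35), creating
genuine trial-to-trial variability in true connectivity. Behavior scores
are a linear read-out of selected true edge strengths
(default: 21 x the RPFC-to-SMA band GC, plus an intercept of 60) with
group-specific noise (sd 3 for experts, 6 for novices), so experts are both
better and more consistent. These defaults were chosen once to produce
realistic observable magnitudes -- edge CoV around 0.4--1, score CoV near
0.07--0.12, and a moderate trial-level brain--behavior $R^2$ on the order
of 0.1 -- and are not adjusted per experiment.

One property of the generator is worth knowing: because connectivity is
estimated *pairwise*, an effect planted on one coupling leaks into every
pairwise GC that shares its nodes (a simulator effect on RPFC-to-LPMC
raises the pairwise RPFC-to-SMA GC through the LPMC route). This is not a
bug but the known non-specificity of bivariate GC; conditional GC, which
would remove it, is deliberately out of scope.

The optics-level forward model (`synthesize_raw_intensity()`) maps each
ROI's HbO2 (and HbR at a fixed ratio, default -0.3) through the modified
Beer--Lambert law to per-channel optical density and intensity
$I = I_0 e^{-\Delta OD}$, over a default montage of 25 long (30--40 mm,
5 per ROI) and 8 short (8 mm) channels. Short channels receive only the
shared systemic component (slow sinusoid at 0.008 Hz plus a Mayer-wave
component at 0.1 Hz) and noise. Optional artifacts: per-channel slow
drifts and seeded motion spikes in optical density. With artifacts off the
preprocessing chain inverts this model to machine precision, which is the
package's strongest end-to-end identity test.

# Preprocessing

The chain is optical density (baselined on the 1-min pre-task rest) ->
Savitzky--Golay motion correction -> zero-phase bandpass -> Beer--Lambert
inversion -> optional short-channel regression -> per-ROI averaging of long
channels. Parameters, with defaults and rationale:

* **Baseline interval**: first 60 s (the pre-task rest). $\Delta OD(t) =
  -\ln(I(t)/\bar I_{\text{base}})$; optical density is kept in natural-log
  units consistently in both the forward and inverse directions.
* **Savitzky--Golay correction**: 3-s window, polynomial order 3, applied
  as fit substitution. The filter reproduces polynomials of its order
  exactly (smooth hemodynamics pass) and attenuates one-sample spikes by
  >80%.
* **Bandpass**: 3rd-order Butterworth, 0.01--0.1 Hz, applied
  forward--backward (zero phase). At a 25 Hz acquisition rate the
  normalized lower edge is 8e-4, so the filter's poles sit ~1e-4 inside
  the unit circle; this amplifies roundoff to ~1e-6 of signal scale, which
  is why the linearity (superposition) property is asserted to 1e-9
  without this stage and to 1e-5 uM with it.
* **Beer--Lambert**: extinction coefficients from the standard tabulation
  (690 nm: 0.350/2.051; 830 nm: 1.058/0.781, in 1/(mM cm)), differential
  pathlength factors 6.4 (690 nm) and 5.8 (830 nm).
* **Short-channel regression** ships but defaults *off*: recordings of the
  kind modeled here include short channels, but their use as regressors is
  not a given; both behaviors are supported.
* **Order**: motion correction and bandpass act on optical density,
  before concentration conversion. A property test verifies the declared
  order by injecting an intensity-level spike and checking it is attenuated
  at the output.

HbR is computed and retained but only HbO2 propagates to connectivity.

# Spectral Granger causality

## Estimator

For each window and each unordered region pair:

1. **Decimation.** The pair's series is subsampled to an analysis rate of
   2.5 Hz. All neural content lies below 0.1 Hz, so nothing in the band is
   lost, while the estimation problem stops being degenerate: at 25 Hz the
   spectral matrix is numerically zero over ~96% of the Nyquist range and
   the factorization cannot converge. Residual broadband noise aliases into
   a flat floor that conditions the factorization.
2. **Cross-spectrum.** The window is linearly detrended as a whole and
   tapered. For a single 54-s window the default is a *sine multitaper*
   estimate (K = 6 orthonormal sine tapers on the full window); for long
   series (at least 8 sub-segments) Welch averaging of Hann-tapered 32-s
   sub-segments with 50% overlap is used instead. Sub-segmenting a 54-s
   window is not viable: periods in the 0.01--0.07 Hz band span 14--100 s,
   so inside a 16--32 s sub-segment that content *is* the trend and
   detrending or tapering destroys it, leaving a near-rank-1 spectral
   matrix. Spectra are zero-padded to a 0.005 Hz grid (13 bins in the
   band) and scaled so the one-sided diagonal integrates to the channel
   variance (Parseval, verified to 10%).
3. **Wilson factorization.** $S(f) = H(f)\,(\Sigma/f_s)\,H(f)^*$ with
   minimum-phase $H$ (identity at lag zero) and innovation covariance
   $\Sigma$ reported in signal units, via Wilson's Newton-type iteration.
   Numerical notes: the causal ("plus") operator must halve the shared
   Nyquist lag as well as the zero lag on an even frequency circle,
   otherwise the iteration stalls at ~1e-5 relative change; a per-channel
   ridge (1e-6 of each channel's mean power) regularizes rank-deficient
   estimates and, being proportional per channel, commutes with channel
   rescaling so GC stays exactly scale-free; convergence tolerance 1e-9
   relative change, max 100 iterations, with an honest `converged` flag --
   unconverged pairs are flagged invalid rather than repaired. On analytic
   VAR spectra the iteration converges in under 10 iterations to
   reconstruction residuals near machine precision.
4. **Geweke decomposition.** For source $s$ and target $t$,
   $$f_{s\to t}(\omega) = \ln\frac{S_{tt}(\omega)}
     {S_{tt}(\omega) - (\Sigma_{ss} - \Sigma_{st}^2/\Sigma_{tt})\,
      |H_{ts}(\omega)|^2}.$$
   $S_{tt}$ is evaluated from the factorization itself, which makes the
   denominator algebraically nonnegative; residual negative values (only
   possible through roundoff) are clipped at zero and counted.
5. **Band average.** Unweighted mean over grid frequencies in
   [0.01, 0.07] Hz, endpoints inclusive.

GC is computed *bivariately* (each pair factorized on its own 2x2
spectrum), matching the pairwise analysis this pipeline models; conditional
multivariate GC is a non-goal. One factorization serves both directions of
a pair.

## Windowing

Trials are cut into nonoverlapping 54-s windows from task onset; the
trial-level analysis uses the first window only, the initial skill-relevant
segment. The 50-s floor reflects the stationarity/resolution trade-off:
below ~50 s the band cannot be resolved at all.

`select_window_length()` implements the stationarity-guided search: the
smallest candidate for which at least 90% of (ROI x window) segments reject
an augmented Dickey--Fuller unit root at alpha = 0.05, computed on the
decimated analysis grid (at the acquisition rate any band-limited signal
looks integrated). The ADF regression uses the drift case with AIC-selected
lag order and Fuller's tau_mu table interpolated in both sample size and
probability; its null calibration is exact (5.0--5.3% rejections on random
walks). Two honest caveats, found during validation and left as documented
behavior rather than patched: (i) the 90%-of-segments bar requires
near-unit per-segment power, so only weakly autocorrelated series (AR
coefficient around 0.1 at the test rate) clear it reliably; (ii)
hemodynamics-like series with realistic persistence essentially never
clear it at 50--60 s, because a 50--125-sample ADF has power well below 1
against stationary-but-persistent alternatives. Production analyses
therefore use the fixed 54-s default, and the selection tool reports
per-candidate pass rates when nothing passes.

## Surrogate null

`gc_surrogate_threshold()` builds a null for one directed edge by circular
shifts of the source channel (offsets at least 10% of the window), which
preserve each channel's spectrum while destroying cross-channel timing.
Under zero coupling the observed band GC exceeds the 200-surrogate 95th
percentile about 5--8% of the time on 54-s windows -- consistent with, if
very slightly above, the nominal 5%, the residual coming from the shared
detrending/taper alignment of the unshifted pair.

## What the estimator can and cannot do at 54 s

A 54-s window carries a time-bandwidth product of roughly 3 in the analysis
band, so single-window GC estimates are intrinsically noisy (SD comparable
to typical values). Validated behavior at the defaults: direction of a
strong unidirectional coupling is recovered in 97--99% of single windows;
rank correlation between estimated and population edge strengths of the
5-ROI default network reaches 0.8 only after averaging ~20 windows; and on
long stationary series (2^14 samples) the estimator matches the closed-form
parametric Geweke oracle to within ~6--9% mean relative error, with
spectral-vs-time-domain consistency well inside 15%. Statistical analyses
of single-window networks therefore lean on the factorial structure and
trial replication, exactly as the CoV chain does.

# Variability and inference

**CoV.** Sample-SD (n-1) over mean across the 5 trials, per subject x
condition, per edge and for the score; undefined when the mean is within
1e-12 of zero (flagged and excluded). Edges with invalid trials are masked
and the CoV computed on the remaining trials when at least 2 are valid.
The n-1 convention follows the small-sample statistical software tradition
these analyses descend from.

**Factorial effects.** The multivariate design is realized as per-DV
univariate two-factor between-subject tests -- the between-subject effect
tables such analyses actually report -- with effects (sum-to-zero) coding
and Type-III sums of squares (the unbalanced-design convention of SPSS),
partial eta-squared = SS_effect/(SS_effect + SS_error), and repeated trials
averaged per subject x condition by default (`trial_as_replicate` pools
trials as rows instead, reproducing larger-df layouts). Type-I error is
calibrated (KS-uniform p-values under the null). A constant DV yields
F = 0 and partial eta-squared = 0 by convention.

**FDR.** Benjamini--Hochberg step-up at q = 0.05, applied per effect family
across the 20 edges; verified identical to the brute-force step-up
definition on random p-vectors.

**Backward elimination.** OLS with iterated removal of the largest
partial-F p-value at or above 0.1. With one true predictor among two pure
noise predictors the expected probability of ending with *exactly* the true
model is about 0.81-0.83 at this threshold (each noise term survives its
final test with probability just under 0.1), so retention rates in the low
0.8s are the calibrated outcome, not a defect.

**Path analysis.** Recursive models fitted equation-wise by OLS
(`skill`/`simulator` effect-coded +-1, then mediating edges, then the
outcome), reporting unstandardized estimates, OLS standard errors, critical
ratios, and two-sided standard-normal p-values -- the convention of
path-analysis software. Joint "every arrow within 2 SE" statements have
probability ~0.95^k for k arrows even for a perfect estimator; calibration
is therefore asserted on pooled per-arrow coverage (~95%) and on the ~5%
false-positive critical-ratio rate under the null.

**Estimated marginal means** come from the fitted factorial models via
`emmeans`, reducing to raw means in balanced designs.

# Pipeline, configuration, and provenance

`run_pipeline()` drives everything from a validated config (YAML or list;
unknown keys rejected; defaults: 54-s window, 0.01--0.1 Hz bandpass,
0.01--0.07 Hz band, DPFs 6.4/5.8, q = 0.05, removal p = 0.1, 5 trials).
Every output table carries a config-hash + seed stamp; identical config and
seed reproduce outputs byte-for-byte; any stage failure removes partial
outputs. ROI-level user data enters through a CSV manifest
(`load_roi_study()`); optics-level data through `preprocess_recording()`.
The exported functions are the interface -- each stage is independently
callable -- and writers emit plain delimited tables plus JSON/YAML
sidecars. (HDF5-based export is not provided; no HDF5 R binding is a
package dependency, and the delimited writers round-trip everything.)

# Problem sizes used in validation

The shipped tests generate everything they use: studies of 2 x 2 subjects
x 2 trials for structural checks and the full 13-subject x 2 x 5 design
for distributional ones; 2^14--2^15-sample series for oracle comparisons
(20 seeds); 100 single windows for directionality; 200 windows x 200
surrogates for null calibration; 200 null replicates for ANOVA
calibration, 1000 random vectors for the BH identity, 100 elimination
runs, and 50 + 100 path-model replicates. The complete suite runs in a few
minutes on one core.

# Known limitations

* Bivariate GC leaks indirect influence (see above); no conditional GC.
* Single-window estimates are noisy by information-theoretic necessity;
  inferences should pool windows, trials, or subjects.
* The ADF-based window screen has low power against persistent stationary
  alternatives at 50--60 s; the fixed 54-s window is the production path.
* The generator's interpolation model is linear, not a hemodynamic
  response convolution; task-evoked transients are out of scope.
* CoV on 5 trials is itself a high-variance statistic; its factorial
  analysis inherits that variance.
* Synthetic data do not emulate optode-coupling changes, cardiac/breathing
  harmonics beyond the Mayer-wave term, or spatially correlated scalp
  physiology, so passing tests demonstrate correctness of the algorithms,
  not robustness to every real-world artifact.
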