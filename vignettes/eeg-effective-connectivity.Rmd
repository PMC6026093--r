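---
title: "Directed EEG connectivity for emotion and stress analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed EEG connectivity for emotion and stress analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`eegconn` estimates *effective* (directed) connectivity between EEG channels
and uses it to classify affective state and long-term stress.  The pipeline
is: amplitude normalization and 4--32 Hz zero-phase band-pass; directed
connectivity per channel pair on a seven-band filter bank (phase slope
index, directed transfer function, partial directed coherence); binary
valence/arousal labelling from SAM self-reports; Fisher-ratio feature
selection; leave-one-out KNN/RBF-SVM classification; and Welch t-tests of
averaged-PSI channel flux between stress groups defined from PSS-14 totals.
A synthetic cohort generator with known directed coupling provides ground
truth for every stage.

# Models and estimators

## MVAR, DTF and PDC

The channels are modelled as a multivariate autoregressive (MVAR) process

$$ w_n = \sum_{r=1}^{m} A^r\, w_{n-r} + \xi_n, \qquad \xi_n \sim N(0, \Sigma). $$

`fitMVAR()` solves the multivariate Yule--Walker system
$\sum_r A^r R(i-r) = R(i)$, $i = 1 \dots m$, built from *unbiased* lagged
covariance estimates, as one block-Toeplitz linear solve; $\Sigma$ is the
covariance of the model residuals.  From the coefficient spectrum
$\bar A(f) = I - \sum_r A^r e^{-i 2\pi f r / F_s}$ and the transfer function
$H(f) = \bar A(f)^{-1}$:

* **DTF** (`dtf()`): $\gamma^2_{j \to i}(f) = |H_{ij}(f)|^2 \big/ \sum_{j'}
  |H_{ij'}(f)|^2$ — influence of source $j$ on sink $i$, normalized over all
  sources feeding the sink.  Rows of the tensor sum to 1 at every frequency.
* **PDC** (`gpdc()`): $|\pi_{j \to i}(f)| = |\bar A_{ij}(f)| \big/
  \sqrt{\sum_{i'} |\bar A_{i'j}(f)|^2}$ — normalized over the sinks fed by
  source $j$; squared columns sum to 1.  `generalized = TRUE` weights
  $\bar A_{ij}$ by $1/\sqrt{\Sigma_{ii}}$ (the GPDC variant).

A point worth knowing: DTF is exactly invariant under a *common* rescaling
of all channels but not under per-channel rescaling (the transfer function
maps $H \mapsto D H D^{-1}$, and the sink-row normalization does not cancel
the source scales).  The variance-weighted GPDC is exactly invariant under
per-channel rescaling, and so is any coherency-based quantity (PSI).  The
[0, 1] amplitude normalization maps all channels onto a common range, so in
practice DTF features are computed on comparably scaled channels, but the
invariance claim should not be over-read; the test suite asserts exactly
what holds.

## Phase slope index

For a channel pair the complex coherency
$c_{ij}(f) = S_{ij}(f) / \sqrt{S_{ii}(f) S_{jj}(f)}$ is estimated from
Welch averaging of Hanning-tapered, disjoint, constant-detrended segments
(`welchCPSD()`), and

$$ \Psi_{ij} = \mathrm{Im} \sum_{f \in F_p} c_{ij}^*(f)\, c_{ij}(f + \delta\!f) $$

is the coherence-weighted average slope of the cross-spectral phase across
the band $F_p$.  With the forward-DFT convention used throughout,
$\Psi_{ij} > 0$ means channel $i$ temporally leads channel $j$ (flow
$i \to j$); the sign convention is pinned by a delayed-copy simulation in
the tests.  $F_p$ contains every bin $f$ with $f \ge$ band low edge and
$f + \delta\!f \le$ band high edge.

$\Psi$ is standardized by a leave-one-segment-out jackknife over the $k_1$
Welch segments, $\tilde\Psi = \Psi / \mathrm{sd}_{jack}(\Psi)$ with
$\mathrm{sd}_{jack} = \sqrt{\tfrac{k_1 - 1}{k_1} \sum_k (\Psi_{(-k)} -
\bar\Psi_{(\cdot)})^2}$.  Under an *instantaneously correlated* null (mixed
sources with no time-lagged interaction — the case the estimator is designed
to reject) $\tilde\Psi$ is approximately standard normal and $|\tilde\Psi| >
2$ is a reasonable significance flag.  Under *exactly independent* channels
the statistic is degenerate (the coherency has zero mean, so $\Psi$ is
quadratic in mean-zero quantities) and the jackknife variance is inflated by
the classic asymptotic factor of about 2: the test is then conservative
(false-positive rate well below the nominal 5%, stable in $k_1$).  This is a
property of the estimator, not an implementation artifact; the test suite
documents it by asserting the nominal band and letting the conservative
behaviour show.

## Feature tables, labelling, classification

Each recording yields $n_v = 7 \times n_c^2$ features per method (seven
4 Hz bands from 4 to 32 Hz, all ordered channel pairs; 448 features for the
8-channel montage).  SAM valence/arousal responses (1--9) are binarized:
$\le 3$ negative/calm, $\ge 7$ positive/excited, the neutral middle is
excluded.  PSS-14 totals are grouped by the sample $\mu \pm \sigma/2$ rule
into stress-free / middle / stressed, with exact (unrounded) cut points.

Classification is two independent binary streams (valence, arousal) fused
into four emotion quadrants.  Features are ranked by the Fisher ratio
$(\mu_1 - \mu_2)^2 / (s_1^2 + s_2^2)$ and the top $n_{out} = 24$ are kept.
Ranking and selection happen *inside each leave-one-out training fold*, as
does z-scoring — selection on the full table leaks the held-out label and is
available only behind an explicit `leaky = TRUE` flag for comparison.
Back-ends: majority-vote KNN ($k = 3$, odd to avoid ties, Euclidean metric
on the standardized features) and soft-margin SVM with Gaussian RBF kernel
$k(x, y) = \exp(-\|x - y\|^2 / 2\sigma^2)$, $\sigma = 6$ for valence and
$3.5$ for arousal, cost 1.  The $\sigma$ parameterization matters: a bare
"sigma" is meaningless without the kernel form, which is fixed here.

## Group statistics

The per-channel *flux* is the net PSI outflow
$\sum_{\mathrm{windows}} \sum_j \Psi_{ij}$ over 25 disjoint 2 s windows
spanning 50 s (`fluxMap()`).  Within each 2 s window the Welch segment
length defaults to window/8 ($\approx$ 0.25 s, $k_1 = 8$, $\delta\!f
\approx 4$ Hz — the filter-bank bandwidth).  This choice came from a
signal/noise analysis of the flux estimator during design: with only 2
segments per window the coherency is so noisy that the flux standard
deviation across subjects is an order of magnitude larger than any
realistic group effect; 8 short segments stabilize it while the phase-slope
signal (which scales with the band integral, not the bin count) is
preserved.  Stressed vs stress-free flux is compared per channel with the
two-tailed unequal-variance Welch t-test; no multiple-testing correction by
default (the comparison spans only 8 channels), Bonferroni/BH behind a
flag.

# The synthetic cohort

The generator (`generateCohort()`) emulates the study conditions the
pipeline targets: 26 subjects, 4 emotional conditions of 60 s each at
250 Hz on the montage {F3, F4, C3, C4, P3, P4, T7, T8} (seven of these
channels appear in the study's group tables; F3 completes the symmetric
10/20 set), plus a resting-state recording.  PSS totals are drawn to match
mean 24 and SD 6.7, with the draw stratified so that the $\mu \pm \sigma/2$
rule reproduces the configured group fractions (0.31/0.38/0.31, the
Gaussian mass split at $\pm \sigma/2$).  SAM responses are the condition's
nominal (valence, arousal) target — (8, 8), (8, 2), (2, 8), (2, 2) — plus
an integer jitter of at most 1, clipped to [1, 9].

Each subject-condition signal is an order-4 MVAR process: every channel has
AR(2) dynamics ($a_1 = 0.5$, $a_2 = -0.2$), and directed edges act at lag 4
(16 ms, a realistic inter-regional conduction delay; a 1-sample delay at
250 Hz would produce a phase slope too small to matter).  Edges form a
front $\to$ central $\to$ parietal $\to$ temporal DAG, so stability holds
for any gain:

* arousal: F3$\to$C3 and F4$\to$C4 at 0.40 (excited) vs 0.05 (calm);
* valence: C3$\to$P3 strong/weak vs C4$\to$P4 weak/strong (left/right
  asymmetry flips with sign);
* backbone: P3$\to$T7, P4$\to$T8 at 0.15;
* stress: a backward edge P3$\to$C3 of 0.30 in every condition, increased
  by $0.30 \times$ `effectSize` for stressed subjects.  Stress therefore
  perturbs the left-parietal outflow without touching the emotion edges.

Per-subject coupling gains share a log-normal jitter (SD 0.1) so subjects
are not identical.  Durations are configurable; the defaults use 60 s
segments (including resting state, of which the flux analysis consumes
50 s) to keep a full default cohort below half a minute of simulation.

What the generator does *not* emulate: ocular/EMG artifacts, volume
conduction and common reference effects, 1/f spectral shape, non-Gaussian
innovations, non-stationarity within a trial.  Passing tests therefore
demonstrate that the estimators and the pipeline recover known directed
structure under the model's own assumptions — not that real EEG of this
kind is classifiable at the same accuracy.  On the synthetic cohort the
default configuration is deliberately well-separated (leave-one-out
accuracies near ceiling); `effectSize = 0` and label permutation provide
the matching null surfaces.

# Numerical choices

* **Spectral grid**: $f_k = k F_s / N$, $k = 0 \dots N/2$ (one-sided).
* **Correlation normalization**: the correlation accessor defaults to the
  unbiased $1/(N-l)$ form; the Wiener--Khinchin spectral route uses the
  biased $1/N$ form, under which the DFT of the (circularly folded) lagged
  correlation equals the periodogram to machine precision — both forms are
  exposed behind a flag.
* **Filtering**: 4th-order Butterworth applied forward--backward
  (zero-phase), mandatory before phase-based estimators; the filter bank
  band-passes the broadband signal once per band.
* **Windows**: 0-based, half-open $[s, s + N)$; the standard analysis
  window is $N = 512$ samples from sample 500 (2.048 s starting at t = 2 s
  — the sample count wins over the nominal "2 s" because it sets the FFT
  size).  Multi-window analyses use non-overlapping contiguous windows.
* **Welch segmentation**: disjoint segments, Hanning taper, constant
  detrend per segment; $L_T$ defaults to 256 samples for feature
  extraction and to window/8 inside the 2 s flux windows (see above);
  $k_1 < 2$ is rejected (jackknife impossible).
* **MVAR order**: default $m = 7$ ($\approx F_s / 32$ taps); `selectOrder()`
  provides AIC/BIC selection when wanted.
* **Degenerate inputs**: constant channels, non-stationary specifications,
  non-positive-definite noise covariances, singular covariance blocks and
  single-class training folds are rejected with diagnostics; zero jackknife
  variance maps the normalized PSI to 0 with a warning; duplicate records
  trigger a twin-leakage warning in leave-one-out evaluation.
* **Ties**: feature ranking breaks ties by feature index; KNN uses odd $k$.

# Problem sizes in the test suite

Unit tests run at reduced scale (8--40 Monte-Carlo replicates, $n$ =
2,000--12,500 samples) chosen so the whole default suite completes in a few
minutes; the acceptance tests use 200 direction-recovery runs, 500
null-calibration runs and 10,000 t-test replicates.  The vignette states
these as the package's own test design.

# Known limitations

* EDF input is not supported; signals are exchanged as wide CSV (time
  column plus one column per channel) and tidy metadata CSV.
* The plain PDC default (rather than the variance-weighted GPDC) follows
  the printed formula of the source methodology; both are available.
* Surrogate-based significance thresholds for DTF/GPDC are out of scope;
  only PSI carries a built-in standardization.
* The jackknife-normalized PSI is conservative under exact independence
  (see above); its calibration is accurate under instantaneous correlation.
* Time-varying (adaptive) MVAR and source-space analysis are not
  implemented.
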