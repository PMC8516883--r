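---
title: "Source-level EEG spectral analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-level EEG spectral analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegspect)
```

eegspect implements a complete resting-state EEG analysis chain at the
cortical source level: sensor-space preprocessing, a standardized
minimum-norm inverse solution over a 68-region atlas, relative band power
(RP), a spatial-entropy statistic (SE) of the regional power distribution,
and nonparametric group comparison. A synthetic cohort generator with
known spectral ground truth makes every stage verifiable without patient
data. This vignette records the models, the tunable parameters, and the
reasoning behind the design choices that were genuinely open.

## The analysis chain

**Preprocessing.** Raw multichannel EEG (microvolts, channels by samples)
passes through, in order: (i) per-channel mean removal; (ii) a 50 Hz
notch; (iii) a 1–70 Hz Hamming-window FIR band-pass; (iv) an optional
artifact-removal hook; (v) segmentation into non-overlapping 5 s epochs;
(vi) automatic rejection of artifact epochs. Both filters are linear-phase
FIRs applied forward–backward, so all attenuation contracts refer to the
net zero-phase response $|H(f)|^2$. The band-pass uses a transition width
of about 1 Hz (roughly 1651 taps at 500 Hz) so that the 1 Hz lower edge is
meaningful; the notch is a band-stop over $f_0 \pm 2$ Hz with a 2 Hz
transition, which suppresses the line tone by far more than 40 dB while
leaving tones 5 Hz away within 1 dB. Filtering is implemented by FFT
convolution with the filter's autocorrelation (the zero-phase net kernel),
with odd-reflection padding to tame edge transients.

Manual steps in the original protocol are replaced by reproducible
surrogates. Independent-component cleaning depends on visual component
selection, so it is exposed only as a pluggable `ica_hook` (default:
identity). Visual epoch rejection is replaced by a deterministic rule: an
epoch is dropped when any channel's peak-to-peak amplitude exceeds 150 µV,
or when a channel's within-epoch SD exceeds the channel's across-epoch
mean SD by more than 4 across-epoch SDs. Both thresholds are arguments.

**Inverse solution.** With lead field $K$ (sensors × sources), centering
operator $H = I - \mathbf{1}\mathbf{1}^\top/m$ (the common average
reference, rank $m-1$), identity noise covariance, and regularization
$\alpha$, the minimum-norm kernel is
$$W = K^\top H\,(H K K^\top H + \alpha H)^{+} H,$$
where $(\cdot)^+$ is the pseudoinverse on the centered sensor space
(singular values below $10^{-10}$ of the largest are treated as zero).
Source estimates $\hat\jmath = W y$ are standardized by the diagonal of
the resolution matrix $WK$ (clipped below at a small positive floor),
which is what yields exact localization of noiseless point sources — a
property the tests verify exhaustively over every source of a toy model.
The default $\alpha = 10^{-8}\,\mathrm{tr}(HKK^\top H)/m$ targets
noiseless validation; noisy data warrant a larger value. Sources are
scalar (fixed orientation). ROI time series are the arithmetic mean of
member-source series (no sign flipping); a "power" aggregation (mean of
per-source standardized power) is available because it is not documented
which of the two the original toolbox chain used.

**Relative power.** Each epoch and ROI gets a Welch PSD: 1 s Hamming
segments with 50% overlap. The 1 s segment length is chosen so that the
1 Hz frequency resolution aligns bins with the integer band edges; a
full-length periodogram is available as an option. The PSD is restricted
to 1–70 Hz and normalized to unit mass, and
$$RP_{band} = \sum_{f \in band} PSD_n(f)$$
with half-open bands $[lo, hi)$ — delta 1–4, theta 4–8, alpha 8–13, beta
13–30, gamma 30–70 Hz — and the last band closed at 70 Hz. This makes the
five bands a partition, so RP vectors sum to 1 by construction. RP is
computed per epoch, then averaged across epochs per ROI.

One discretisation subtlety: at the 1 Hz grid the closed upper edge gives
gamma 41 bins out of 70, so a perfectly flat spectrum yields RP
$(3,4,5,17,41)/70$ rather than the continuous bandwidth ratios
$(3,4,5,17,40)/69$; the difference is at most 0.006. Tests against the
continuous ratios therefore use a 0.012 absolute tolerance, which also
covers Welch sampling noise. A related smearing effect: band-limited
signal energy within half a bin of a band edge is split with the
neighbouring band, so e.g. a purely alpha-band signal (5 bins wide) shows
RP$_\alpha \approx 0.8$–$0.95$ per ROI rather than exactly 1.

**Spatial entropy.** For each band and epoch, the 68 ROI RP values are
histogrammed with Freedman–Diaconis binning — width
$h = 2\,\mathrm{IQR}\,n^{-1/3}$, quartiles by linear interpolation of
order statistics (R's type-7 quantiles; bin counts depend on this choice,
so it is fixed and documented), equal-width bins spanning the data range,
last bin right-closed, a single bin when the IQR is zero — and
$$SE = -\frac{1}{\log N}\sum_{n=1}^N p_n \log p_n \in [0, 1],$$
with $0\log 0 := 0$ and $SE := 0$ for a one-bin histogram. The printed
form of the defining equation lacks the Shannon minus sign (as written it
would be non-positive); the implementation uses the standard sign so that
the statistic matches its stated interpretation, low for homogeneous
regional distributions. The natural logarithm is used; the normalization
makes the ratio base-invariant. SE is computed per epoch and averaged.

An important property discovered while validating the generator: SE of
the FD histogram is *affine-invariant*, so it measures histogram *shape*,
not spread. Sixty-eight iid noisy values of any scale already produce a
near-uniform histogram ($SE \approx 0.9$); exact spatial homogeneity gives
$SE = 0$ discontinuously; and increasing log-normal dispersion makes the
value distribution more skewed, concentrating mass in few bins and
*lowering* SE (measured seed-averaged values fall from about 0.90 at
dispersion 0 to about 0.65 at dispersion 2). The intuition "more spatial
heterogeneity, higher SE" holds only through the shape channel, not the
scale channel. The property tests assert this computed direction.

**Group statistics.** Exploratory Kolmogorov–Smirnov (against the fitted
normal) and Levene (Brown–Forsythe) checks are advisory only; the
comparison is always nonparametric, as in the study the pipeline
reproduces. The Mann–Whitney U test uses the exact null distribution when
$n_1 + n_2 \le 20$ with no ties, otherwise the normal approximation with
tie and continuity correction; the reported U is that of the first-listed
(risk) group, a convention that the printed values of the original
analysis cannot disambiguate, so it is configurable. Three families are
tested per band: a global test on subject-level ROI-averaged RP, per-ROI
tests corrected by Benjamini–Hochberg step-up FDR *within* the band's 68
ROIs (one family per band, not pooled across bands), and a test on SE.
Demographic matching uses Pearson's chi-square without continuity
correction.

## The synthetic cohort generator

Each cortical source carries one band-limited Gaussian oscillation per
band plus a $1/f$ background between 1 and 70 Hz, with sensor data
obtained through the toy lead field (sources on a unit sphere, sensors on
a concentric shell, inverse-square gains). Band-limited components are
synthesized directly in the frequency domain: flat spectral mass over
exactly the band's DFT bins (same half-open edge convention as the
analysis side), random phases, calibrated so the time-domain variance of
band $b$ equals the squared amplitude $a_b^2$ exactly in expectation.
This makes the spectral ground truth sharp — the fraction of signal
variance in band $b$ is $a_b^2 / \sum_c a_c^2$ — which an FIR-filtered
white-noise construction would blur through its transition bands, and it
is also what keeps cohort-scale simulation affordable.

Structure of the amplitudes for subject $i$, ROI $r$, band $b$:
$$a_{irb} = A_b \cdot m_b^{[\text{risk}]} \cdot u_{ib} \cdot v_{irb},$$
with defaults chosen once, before the validation studies were frozen:

* $A_b$ (µV RMS at the source): delta 0.45, theta 0.35, alpha 0.55, beta
  0.33, gamma 0.18 — an alpha-dominant, elderly-eyes-closed-like
  composition in which beta carries roughly 15% of total power;
* $m_b$: per-band effect multipliers applied to the risk group only
  (all 1 by default; the study the pipeline models reports no
  quantitative effect size, so non-unit values are illustrative);
* $u_{ib} = e^{\sigma_s Z}$: per-subject log-normal band-amplitude
  variability, $\sigma_s = 0.2$, giving a power ratio of about 2.2×
  between ±1 SD subjects — consistent with the large between-subject
  variability of resting band power;
* $v_{irb} = e^{h_b Z}$: per-ROI log-normal spatial heterogeneity,
  $h_b = 0.3$;
* $1/f$ background RMS 0.5; 300 s at 500 Hz by default.

`subject_sd` ($\sigma_s$) exists because without it a 53-subject cohort
is between-subject nearly deterministic — the per-ROI draws average out
as $1/\sqrt{68}$ — which no real cohort resembles and which would make
arbitrarily small mean shifts detectable. Its default was fixed by a
design simulation run before the validation suite was written, balancing
detection of a beta effect against the compositional leakage described
next, and was not revisited afterwards.

**Compositional leakage.** RP sums to one, so multiplying the risk
group's beta source power by $0.64$ (amplitude ×0.8) necessarily *raises*
every other band's relative power by the total-power factor $T/T'$. The
standardized contrast of the direct beta effect versus the induced shift
in band $x$ is bounded by roughly
$(1 - RP_\beta)/RP_x \cdot (\sigma_x/\sigma_\beta) \lesssim 4\text{–}6$,
so any configuration in which the beta effect is detected with $\ge 80\%$
power leaves the most sensitive other bands rejecting at roughly 8–15%
rather than the nominal 5%. This is a property of relative power itself,
not of the generator — the original study shows the same coupling, with
delta nearly significant alongside its beta effect. The validation suite
therefore asserts that the beta test attains its target power while the
other bands stay far below it (at most 0.25), rather than asserting an
unattainable strict 5%.

What the generator does *not* emulate: realistic head geometry and volume
conduction (the forward model is a toy), eye-blink or muscle artifacts (a
transient injector exists solely to exercise the rejection rule),
non-stationarity, drowsiness, and 1/f exponents other than 1. Passing
tests therefore validate the computational chain and its statistical
calibration, not claims about real patient EEG.

## Numerical choices and problem sizes

Pseudoinverse tolerance $10^{-10}$ relative; resolution diagonal floored
at $10^{-12}$ of its maximum; RP normalization rejects spectra with no
mass in 1–70 Hz; empty epoch sets are rejected downstream while full
rejection of a subject's epochs excludes the subject with a logged
warning. Degenerate histograms (constant input) define $SE = 0$.
Ties in the U test switch to the corrected normal approximation; BH flags
are computed by the explicit step-up rule and agree with adjusted
p-values ≤ q by construction.

The Monte-Carlo studies in the validation suite use 68 ROIs and the
study's 18 vs 35 group split at 500 Hz: the type-I calibration of the
global test runs 500 cohorts of single-epoch (5 s) subjects — calibration
of a rank test does not depend on the epoch count — and the power study
runs 150 cohorts of two-epoch (10 s) subjects, where the beta effect is
detected above the targeted 80% rate. `power_study()` batches the FFT
work of all subjects (FFTW kernels under `src/`) and is proven equal to
the explicit per-subject chain in the tests; these sizes keep a full
calibration run in the minutes range on a single core. Larger studies
scale linearly.

## Known limitations

* Recordings are read from plain ASCII/CSV matrices (the storage format
  of the study's data); EDF input is not implemented.
* The forward model is a sphere-based toy; results about localization are
  statements about the inverse algebra, not about anatomical accuracy.
* Scalar sources only; free-orientation (3-component) source spaces are
  out of scope.
* The SE statistic's behaviour under dispersion is shape-driven (see
  above); comparisons of SE across cohorts with very different spatial
  value distributions should be interpreted with that in mind.
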