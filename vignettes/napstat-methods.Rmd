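---
title: "Methods: nap physiology, dream reports and score gains in napstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nap physiology, dream reports and score gains in napstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napstat)
```

napstat implements a complete analysis chain for nap studies relating sleep
physiology and dream content to behavioral score gains: signal cleaning,
band-power spectra, slow-wave and spindle detection, heart-rate
variability, rater-consensus dream properties, game scores, and
permutation-corrected correlation topographies. This vignette documents the
models and procedures, the parameters that matter, the synthetic-cohort
generator that stands in for participant data, and the numerical and design
choices made where the procedure left them open.

## The statistical core

The quantity of interest is the Spearman correlation between a behavioral
score gain and each member of a *family* of features — for example, the 55
channels of Delta-band power in one participant group. Testing a family
inflates the false-positive rate, so adjusted p-values come from a
max-statistic permutation scheme: the outcome vector is permuted P times
(P = 100,000 at study scale; tests use smaller P), each permutation records
the maximum |rho| across the family, and the adjusted p for feature *f* is

> p_adj(f) = (1 + #\{permutations with max |rho| ≥ |rho_f|\}) / (P + 1).

The add-one convention keeps p strictly positive (floor 1/(P+1)) and makes
the test valid at finite P. Because every feature is compared against the
same family-wise null, |rho| ordering implies p ordering, and the family
adjusted p dominates any single-feature permutation p. Significance is
declared at adjusted p < 0.05.

Partial Spearman correlations (covariate sets ∅, R1 = round-1 score, Exp =
experience metric, or both) rank-transform all variables, residualize the
ranked feature and outcome on the ranked covariates by least squares, and
correlate the residuals. The permutation null uses Freedman-Lane
residualization: outcome-rank residuals from the covariate-only model are
permuted, added back to the reduced fit, and the full statistic is
recomputed, with the same max-|rho| family correction. With an empty
covariate set the code path reduces exactly to the unadjusted family.

One design question the procedure leaves open is family granularity —
whether correction spans channels within one band or channels × bands
jointly. napstat corrects within one (band or property) × group family,
matching per-band topographies; the family label is carried in every output
row so any other grouping can be assembled and rerun.

## EEG cleaning

The ten-step pipeline runs in a fixed order (outputs are defined only for
this order): channel subset → average re-reference, re-adding the original
reference electrode (FCz) as a data channel → 1–250 Hz bandpass → 60 Hz
removal → two-pass bad-channel rejection → ICA ocular removal → amplitude
and normalized-power artifact masks → saturated-channel drop with mask
recomputation → spherical-spline interpolation → 40 Hz low-pass. Filters
are zero-phase forward-backward order-4 Butterworth; when the nominal
250 Hz upper edge is at or above Nyquist (any recording at ≤ 500 Hz) only
the high-pass section applies.

**Re-referencing.** Each channel becomes its value minus the
across-channel mean and the reconstructed reference equals minus that mean.
Note the output column mean is not zero: it equals the reference divided by
n + 1, because the reference is the average of the *n data channels*, not
of all n + 1 — the convention under which the former reference carries a
meaningful signal.

**Line noise** is removed by sliding-window (4 s, 50 % overlap)
sine-plus-cosine regression at the target frequency with Hann cross-fading
— a deterministic narrowband method: tones 2 Hz away change by well under
1 dB. Harmonics are configurable (default: 60 Hz only).

**Bad channels** are screened twice from log total power in 1–125 Hz.
Small montages forced two refinements of the plain "3 sd from the mean"
rule. First, a pooled z-score of n channels is algebraically bounded near
√(n−1), so one gain-corrupted channel among 9 can never exceed 3; the
center is therefore the across-channel median and the scale the sd of the
*other* channels (leave-one-out), which preserves the motivation for the
second pass — an extreme channel inflates the scale for the rest in pass 1
and its removal exposes moderate outliers in pass 2. Second, the scale has
an absolute floor (`badchan_min_sd`, default 0.2 log10-power ≈ 2 dB):
sub-4× power differences are normal inter-electrode variation and are never
flagged, which is what keeps the false-positive rate at zero on
homogeneous synthetic montages where any scale-free rule would flag ~20 %
of recordings. Bad channels differ by orders of magnitude, so detection is
unaffected. Flat channels are floored at 10⁻¹² µV² before the log so
flatlines flag as low outliers; zero spread flags nothing. A caveat
documented here deliberately: after average re-referencing, k equally
corrupted channels among n leak into every channel and their log-power
contrast saturates near 1.4 for k = 2, n = 9 — multi-channel corruption is
reliably detectable at the 55-channel study montage, not in the 8-channel
test montage.

**Ocular removal** uses an in-package symmetric fixed-point FastICA
(logcosh contrast, seeded initialization). Each component gets an ocular
pseudo-probability in [0, 1]: half the frontal concentration of its mixing
column over Fp/AF channels, half its power fraction below 5 Hz; components
above 0.5 are zeroed. The scorer is a pluggable function, so a trained
classifier can replace the heuristic without touching the pipeline. When
most sources are near-Gaussian the Gaussian subspace has no preferred
rotation and the iteration cannot fully converge; following common
practice the decomposition then warns and returns the usable estimate
rather than failing, and errors only if the unmixing matrix degenerates.

**Artifact masks.** A sample is an amplitude artifact iff |x| strictly
exceeds 100 µV — a sample at exactly 100 µV is clean — and flags dilate by
±200 ms, clipped at record edges (at 250 Hz a single spike flags exactly
101 samples). The power criterion z-scores log power of non-overlapping
2-s epochs within each channel and flags epochs more than 3 sd *above* the
mean; the channel criterion is two-sided but the epoch criterion one-sided,
following the respective wordings. The epoch grid anchors at block start
and a trailing partial epoch is always flagged. Channels flagged on more
than 20 % of samples (strict) by the amplitude criterion are dropped, and
both criteria are recomputed on the survivors to give the final mask.

**Interpolation** reconstructs rejected channels with order-4 spherical
splines (Legendre series truncated at 50 terms) from all good channels;
positions come from an azimuthal-equidistant inverse projection of the
flattened 10-10 grid (18° of arc per 10 % step), which reproduces smooth
scalp fields to within 5 % RMS — adequate since only inter-electrode
angles enter the kernel.

## Spectra

Artifact-free 2-s segments are taken from block start; a segment survives
only if *no* channel is flagged at *any* sample inside it (the any-channel
rule, so all channels share one segment set). Per segment and channel a
Hann-tapered periodogram is computed; the two native 0.5 Hz bins around
each integer frequency aggregate into integer-centered 1 Hz bins; linear
PSDs average across segments *before* the dB transform (the stated order:
computed for valid segments, then transformed). Band power is
10·log10(Σ bins + 10⁻¹²), a band with half-integer edges (l, h] collecting
integer bins l < b ≤ h: Delta = {1,2,3}, Theta = {4..7}, Alpha = {8..12},
Sigma = {13..16}, Beta = {15..30} — bins 15 and 16 belong to both Sigma
and Beta, an intentional overlap.

## Sleep events

**Slow waves.** The signal is bandpassed 1–3 Hz with stopband edges 0.1
and 3.9 Hz; a zero-phase FIR (4·rate taps, Hamming) meets the ≥ 20 dB
stopband attenuation within the 0.9 Hz transition bands. Within each
artifact-free 6-s epoch, one wave = the negative half-wave plus its
rebound peak — the pair of half-waves straddling a negative-to-positive
zero crossing, delimited by the surrounding positive-to-negative crossings
(epoch edges also delimit). A candidate is kept if its full period lies in
0.33–1.0 s and its trough-to-peak amplitude reaches the threshold (default
0 µV since the source procedure states none; a 75 µV AASM-style option
exists, and detector studies here use 20 µV over a quiet background). Per
epoch the mean amplitude, count and summation (count × mean amplitude) are
computed — empty epochs contribute zeros, since the average runs over *all*
valid epochs — then averaged per channel; the identity summation = density
× mean amplitude holds exactly per epoch before averaging. Amplitude
statistics stay in µV (an optional dB transform of summaries exists but is
off by default; the source's remark about a dB conversion is ambiguous and
is logged as such).

**Spindles.** An A7-style detector computes four features on 0.3-s windows
stepped by 0.1 s: absolute sigma (11–16 Hz) power (log10 µV²), relative
sigma power (z-scored log ratio to 0.5–30 Hz broadband power), sigma
covariance (z-scored log covariance of sigma-filtered and broadband
signals), and sigma correlation. All four must exceed their thresholds
(published defaults 1.25, 1.6, 1.3, 0.69); contiguous windows merge, events
must last 0.3–2.5 s, events intersecting any artifact flag are discarded
entirely (not truncated), and only events whose onset epoch matches the
requested stage are kept. Detection runs on all channels. Per channel and
stage the count and mean duration are reported; channels with no events
report (0, 0), and a subject with no events on any channel is excluded
from that stage's analysis.

## Heart rate

Pan-Tompkins: 5–15 Hz bandpass, derivative, squaring, 150-ms
moving-window integration, adaptive dual thresholds with search-back and a
0.2-s refractory period; beat times refine to the bandpassed local maximum.
The interactive extreme-inspection loop of the original procedure is
automated with identical removal semantics: repeatedly examine the current
minimum and maximum inter-beat interval; if it violates physiologic bounds
(0.3–2.0 s) or lies more than 5 MADs from the series median (when the MAD
is zero — a majority of identical intervals — any deviation counts), remove
it *and both neighboring intervals*; iterate until the extremes pass.
Segments left with one interval are deleted and neighboring segments are
bridged by one spline-interpolated point, yielding a single continuous
series; more than 50 % removal marks the ECG unusable.

The 11 metrics: rangeIBI, meanIBI, medianIBI, sdIBI, RMSSD, meanHR and
sdHR from instantaneous HR = 60/IBI per beat (not windowed), HRVTi = IBI
count / modal count of the 1/128-s-bin histogram, and spectral metrics from
the IBI series resampled at 4 Hz by cubic spline with a Hann-segment Welch
PSD: LF = 0.04–0.15 Hz, HF = 0.15–0.4 Hz, nLF = 100·LF/(LF+HF),
nHF = 100·HF/(LF+HF) (so nLF + nHF = 100 whenever defined), LFHF = LF/HF;
band edges and resampling rate follow common HRV-toolbox conventions and
are configurable since the source does not state them. Zero total LF+HF
power leaves the spectral metrics missing.

## Reports, scores, covariates

Raters answer seven statements on a 1–6 agreement scale; a rater whose
statement-1 answer is ≤ 3 leaves statements 2–7 blank. Blanks are filled
with 3.5 *at rater level, before* the median (the filled value is the
rater's answer); a blank alongside statement-1 agreement is unexpected —
it warns and is still filled — and a blank statement 1 is an error. The
consensus is the per-statement median (even rater counts average the middle
two) and a report is a dream iff the statement-1 median is ≥ 3.5.
Agreement uses the two-way random-effects, absolute-agreement, single-rater
ICC — the most conservative common form for "agreement between raters",
since the source cites the guideline but not the form — computed from the
mean-squares decomposition, with the average-measures form available and
the form recorded in every output row. Labels: below 0.50 poor, then
moderate, good, and excellent above 0.90, boundaries assigned to the upper
bin. Zero between-report variance leaves the ICC undefined.

Scores: prey = collections − losses, predator = wins − losses, gain =
round-2 score − round-1 score. Exp z-scores each of five experience
questions within role and sums them, so Exp sums to zero within role; a
zero-variance question contributes 0 for all subjects of that role.

## The synthetic cohort

The generator emulates the study conditions at test scale and its defaults
are fixed: 8 named channels of the 55-channel 10-10 montage at 250 Hz (the
full montage and the 1000 Hz acquisition rate are reachable by
configuration; every operator is rate-agnostic), a 130-min nap opportunity,
and a semi-Markov hypnogram — per-stage normal dwell times rounded to whole
30-s epochs (floored at one), an embedded transition matrix, a burn-in of
one nap length so occupancy is stationary, and dwell means (W 480 s, N1
90 s, N2 180 s, SWS 150 s, REM 360 s) chosen to give the wake-rich,
SWS-poor occupancy typical of a stressful daytime nap. The exact stationary
occupancy (embedded-chain stationary distribution weighted by the exact
expected dwell in epochs) is exported as the Monte-Carlo oracle for the
hypnogram tests.

EEG background is 1/f noise with a common volume-conducted source
(`spatial_corr` = 0.6) — without spatial correlation the reconstructed
average-reference channel is a systematic low-power outlier, an artifact no
real montage shows. Planted events are stage-gated and ledgered exactly
once each: slow waves as single-cycle 2 Hz trough-then-peak waveforms
(amplitude ~ N(80, 15) µV; 2 Hz sits at the center of the 1–3 Hz detection
band — a 1.25 Hz single cycle has most of its spectral mass below the band
and is split by any band filter), spindle bursts (11–16 Hz, Hann-tapered,
default 30 µV), and occipital-dominant waking alpha. Artifacts on demand:
60 Hz line, high-amplitude transients, gain-corrupted bad channels, and a
frontal-dominant ocular blink source. The ECG is a QRS-template train whose
inter-beat intervals follow baseline + LF (0.1 Hz) + HF (0.25 Hz) sinusoids
plus jitter, with exact beat times ledgered. No amplitude or density
figures for the study's own participants exist, so event defaults are
literature-typical; they are conditions, not tuning knobs.

Rater forms discretize Gaussian noise around integer latent Likert values
(clipped to 1–6) and apply the blank rule; game counts are role-asymmetric
Poisson draws (predators out-win, prey out-collect) whose round-2 counts
are adjusted so the realized integer gain tracks the planted effect:
gain ∝ effect weight × z-scored planted slow-wave summation + a latent
dream-about-game component calibrated on the Spearman scale via the normal
copula (ρ = 2 sin(π r_s / 6)) + noise. Rounding to integer counts and the
non-negativity clip attenuate planted correlations slightly (≈ 0.77
realized for a 0.8 target at n = 200), which the ±0.1 recovery tolerance
absorbs.

For many-seed parameter-recovery studies the full signal path is
unnecessary: `generate_cohort_summaries()` draws the *planted* per-channel
slow-wave summation directly from a log-normal channel model with a shared
subject factor (bystander loading 0.9 — slow-wave production is dominated
by a subject-level trait, so per-channel summaries are nearly collinear
across subjects) and a gain with the target Spearman correlation. The
signal path itself is exercised by the detector-recovery and end-to-end
determinism studies.

What the generator does **not** emulate: K-complexes, arousals,
slow-oscillation/spindle coupling, realistic EDF annotations, non-stationary
electrode drift, or any text of the dream reports (the analysis starts at
the Likert matrix). Passing tests therefore certify the pipeline's
contracts — orders, thresholds, formulas, error control, determinism — on
signals whose ground truth is known, not detector performance on real
polysomnography.

## Fixture sizes and numerical choices

Test and acceptance studies use scaled-down problem sizes chosen as the
package's own fixtures: 60–120 s single-channel recordings for detector
recovery (50 seeds), 120-s 8-channel naps for pipeline QC, 200 hypnograms
for the occupancy check, P = 2,000–20,000 permutations against the
exhaustive n = 7 oracle (5040 orderings), 500 null cohorts for family-wise
error, 100 seeded cohorts at n = 13 / P = 5,000 for effect recovery, and a
4-subject cohort with 2-minute naps run twice for byte-level determinism.
The slow-wave recovery fixture plants 2 Hz waves ≥ 40 µV over a 3 µV
background with a 20 µV detection threshold; the spindle fixture plants
0.8–1.5-s bursts at 2 per minute over 240 s and 30 µV over a 10 µV
background — typical N2 morphology well above the A7 window floor; the
longer fixture keeps the detector's adaptive (z-scored) feature baselines
stable, which short event-dense segments bias.

Numerical conventions collected in one place: strict inequalities at the
100 µV amplitude threshold, the 20 % drop fraction and the 3-sd criteria;
boundaries of the ICC label bins belong to the upper bin; dB floors of
10⁻¹² µV² keep silent channels finite; tie handling is mid-rank
everywhere; the permutation p floor is 1/(P+1); EDF headers carry fixed
date fields so identical recordings write byte-identical files; every
random draw descends deterministically from a user seed, with independent
per-component substreams.

## Known limitations

* The ocular scorer is a two-feature heuristic, not a trained classifier;
  its contract (pseudo-probability in [0, 1], 0.5 threshold) matches the
  original tool but its decisions on real mixed artifacts will differ.
* Multi-channel corruption detection degrades in montages of ≤ 10 channels
  (contrast saturation through the average reference, above).
* The slow-wave detector reproduces the *described* modifications (band
  edges, 6-s epochs, summary statistics); the source algorithm's own
  duration and amplitude criteria are not public, so defaults here are
  explicit substitutions.
* HRV spectral band edges and resampling follow toolbox conventions, not a
  stated specification.
* At 4-subject demo scale nothing can reach significance; the statistical
  machinery is meaningful from n ≈ 7 upward (exhaustive-oracle scale) and
  study-powered at n = 13 per group.
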