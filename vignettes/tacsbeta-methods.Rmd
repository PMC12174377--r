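---
title: "Methods: sensorimotor beta power, peak-frequency and cluster statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensorimotor beta power, peak-frequency and cluster statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tacsbeta` analyses how weak 20 Hz transcranial alternating current
stimulation (tACS) over the left primary motor cortex changes sensorimotor
EEG power. It implements the full analysis chain of a typical
within-subject aftereffect study — four stimulation intensities (sham,
0.5, 1.0, 1.5 mA), three measurement blocks (pre, post1, post2), resting
and self-paced finger-press recordings — together with a seeded synthetic
generator so that every stage can be validated by parameter recovery. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## The signal model behind the generator

Each simulated channel is the sum of a `1/f^x` pink-noise background
(default exponent 1, SD 1.5 µV, flattened below 0.5 Hz where acquisition
high-pass filters dominate real recordings) and band-limited oscillations:
theta at 6 Hz, alpha at 10 Hz, gamma at 70 Hz, and beta at the subject's
peak beta frequency, drawn uniformly from 15–25 Hz so that a cohort
straddles the 20 Hz stimulation frequency. Oscillations are sinusoids with
a random phase per trial, mixed into the seven-electrode clusters centred
at C3 and C4 with gains of 1.0 at the centre electrode and 0.8 at its six
neighbours. Because ROI averaging is the only spatial operation
downstream, no volume-conduction modelling is attempted.

Movement-locked dynamics use a piecewise amplitude envelope per press:
pre-movement (−500–0 ms) and movement (0–500 ms) at `1 − erd_depth`,
post-movement (1500–4000 ms) at `1 + ers_gain`, joined by raised-cosine
ramps placed in the gaps (−700 to −500 ms, 500 to 1500 ms, 4000 to
4300 ms). Both ERD depth and ERS gain act on the *amplitude* envelope, so
the expected baselined power is closed-form: an amplitude factor `a` over
a period yields `20·log10(a)` dB. With the default `erd_depth = 0.4` the
movement-period beta power is `20·log10(0.6) ≈ −4.4` dB; an injected
depth of 0.5 gives `10·log10(0.25) ≈ −6.02` dB.

Injected stimulation aftereffects are multiplicative on linear power,
keyed by (time point, band, region, resting-or-period), plus an additive
peak-frequency shift per time point. Amplitudes are scaled by the square
root of the multiplier, so a power multiplier `m` is recovered as a factor
`m` in measured wavelet power. Sham is the identity. The default study
configuration injects *no* effects — recovery tests state their injections
explicitly.

The oscillation amplitudes (theta 1.5, alpha 2, beta 4, gamma 1 µV
against 1.5 µV pink noise) were fixed once, for testability rather than
cohort realism: the closed-form recovery checks need the noise power
collected by the beta-peak wavelet (whose spectral SD is `f/cycles`,
roughly 4.5 Hz near 17 Hz) to stay below a few percent of the oscillation
power. Real sensorimotor recordings have lower beta SNR; the generator
makes the arithmetic of the pipeline checkable, it does not emulate
cohort-level effect sizes.

The force trace is sampled at 5000 Hz and holds one Gaussian pulse per
press (peak 2 N, σ = 80 ms) over a 5 mN sensor-noise floor. The pulse is
positioned so that its threshold crossing (default 0.5 N) sits exactly at
the recorded ground-truth onset, exercising the first-sample-above-
threshold trigger rule with a controllable crossing.

## Preprocessing

Raw recordings (1000 Hz) are band-pass filtered 0.5–95 Hz and notch
filtered at 50 Hz, both zero-phase (forward–backward application), then
decimated by 2 to 500 Hz. The band-pass is a 4th-order Butterworth
low-pass cascaded with a 2nd-order Butterworth high-pass; the notch is an
RBJ biquad with Q = 30. Zero-phase application avoids latency distortion
of the ERD/ERS timing; a linear-phase FIR with a 0.5 Hz transition edge
would need several thousand taps at 1 kHz for no analytic benefit here.
The 95 Hz low-pass doubles as the anti-alias filter for the factor-2
decimation (new Nyquist 250 Hz).

Resting recordings are cut into consecutive non-overlapping 2000 ms
segments; event recordings into −2500 to 4500 ms epochs time-locked to
the detected press onsets (onsets too close to the recording edges are
dropped with a warning). Visual trial screening is replaced by an
automated peak-to-peak criterion: any trial exceeding 200 µV on any
channel is flagged. Datasets with fewer than 11 kept trials are excluded;
datasets below 20 kept trials are marked `below_recommended`. ICA-based
artifact subtraction is intentionally absent: the synthetic data contain
no ocular or myogenic components, and the pipeline records where such a
hook would sit.

## Time–frequency decomposition

The engine uses complex Morlet wavelets at 4–90 Hz in 1 Hz steps
(87 frequencies). "Logarithmically increasing" cycles are implemented as
geometric interpolation, `c_i = 3·(13/3)^(i/86)`, which is the standard
reading in the time–frequency literature and the only smooth schedule
hitting both printed endpoints (3 cycles at 4 Hz, 13 at 90 Hz) exactly.
Each kernel is a Gaussian-windowed complex exponential with temporal SD
`σ_t = cycles/(2πf)`, truncated at ±4 σ (odd length) and normalised to
unit energy. Power is the squared magnitude of the analytic signal.

Edge artifacts are handled by the interior-window strategy: epochs are
convolved in full, but power is sampled only on 20 ms grids away from the
edges — 400–1600 ms within each 2000 ms resting segment (61 points) and
−500 to 4000 ms for event epochs (226 points), with the baseline sampled
at −2000 to −1000 ms. The implementation refuses grid points closer to an
epoch edge than 3 temporal SDs of the longest wavelet; at 4 Hz and
3 cycles this allows the 400 ms margin the protocol uses while keeping
more than 99% of the kernel mass inside the epoch.

Cluster (ROI) averaging is arithmetic, on linear power, before any dB
conversion — following the stated order of operations. dB uses the power
convention `10·log10`. Event-related power is baselined per trial, ROI
and frequency by the mean linear power over −2000 to −1000 ms of the same
trial; the companion `baseline_ratio()` keeps the same normalisation on
the linear scale for the statistics stage. Trial-wise (rather than
condition-average) baselining was chosen for statelessness: each trial's
record is computable in isolation. Band/period aggregation averages dB
values over the band's integer-Hz bins (theta 4–7, alpha 8–12, beta
13–30, gamma 60–90; 31–59 Hz deliberately unassigned) and the period's
grid points; period windows are left-closed/right-open except the last
(post-movement) so adjacent periods never share a grid point.

## Peak beta frequency and percent change

The per-trial peak beta frequency is the beta-band frequency with the
greatest ERD (most negative period-mean baselined power) in the
pre-movement and movement periods, or the greatest ERS (most positive) in
the post-movement period; the spectrum is averaged over the period's time
points before taking the extremum, and ties resolve to the lower
frequency. The endogenous–exogenous difference subtracts the 20 Hz
stimulation frequency.

A resolution caveat documented here because it shapes the validation: at
beta frequencies the protocol's wavelets have a spectral SD of roughly
4–5 Hz, so a 1 Hz-wide modulated oscillation produces an essentially flat
baselined ERD/ERS profile across the beta band (flat to ~0.001 dB in
noise-free simulation). The per-trial extremum is therefore allocated by
noise within that plateau, and its trial median carries a bias of 2–3 Hz
toward bins with higher noise variance. The synthetic validation
consequently checks (a) that the *spectral* peak — the argmax of
trial-averaged absolute beta power — recovers the injected frequency
within ±1 Hz, and (b) that an injected peak shift moves the ERD-weighted
estimate in the injected direction under a matched noise realisation. In
real recordings, where modulation depth varies across the beta band, the
ERD-weighted definition carries more information than it can for a
single synthetic tone.

Percent-change maps between measurement blocks are computed element-wise
as `100·(b − a)/a` on trial-averaged *linear* baseline-ratio maps —
percent of a signed dB quantity is ill-defined — with reference elements
below a configurable floor set to missing and counted.

## Mixed-effects stage

Trial-level power is modelled with a Gaussian generalized linear mixed
model with a log link and a participant random intercept, the model
family reported for this design; term tests are type-II Wald chi-squares.
The response is strictly positive by construction: raw linear power
(µV²-scale) for resting data and the baseline ratio for event-related
data, making the log link valid (dB values can be negative and are not).
`glmmTMB` is the primary backend; when it fails or does not converge —
or when many simulated cohorts must be fitted quickly — a linear mixed
model on `log(power)` (`lme4::lmer`) is used and the substitution is
recorded in the fit descriptor. On lognormal data the two parameterise
the same conditional-median structure.

Contrasts are pairwise comparisons of estimated marginal means on the
link scale with Bonferroni correction within each family, asymptotic z
tests, and effect sizes standardised by the model residual SD. Because
baseline power can differ between stimulation intensities, intensities
are never compared directly: the `intensity_change_scores` family
compares each intensity against sham on the *change* between two time
points (interaction contrasts). AIC is recorded for the fitted family
rather than searched over, since the family is fixed by design.

## Cluster-based permutation correlations

For each movement period, region, stimulation intensity and block pair,
the per-subject pre-stimulation endogenous–exogenous frequency difference
is correlated (Spearman's ρ, average ranks) with each pixel of the
per-subject percent-change maps. Pixels with p < 0.05 are clustered by
spectral-temporal adjacency — 4-connectivity on the (1 Hz, 20 ms)
lattice, no diagonal joins, positive and negative ρ never joined — and
each cluster's mass is the sum of |ρ| over its members. Each permutation
shuffles the subject-to-scalar assignment, recomputes the map and
clusters, and contributes its largest mass (0 if none) to the null;
observed clusters of either sign are significant if their mass exceeds
the null's 97.5th percentile. One pooled null serves both signs — the
literal reading of the stated procedure; with two-sided pixel tests this
makes the per-test familywise error rate ~2.5–5%, and the measured
global-null FWER is ~2–3%.

Pixel p-values come from the exact permutation distribution of ρ (full
enumeration, ties respected) when n ≤ 9 subjects and from the
t-approximation otherwise; the same rule is used inside the permutation
loop so observed and null clusters are thresholded identically. The
permutation count (default 1000; 200 in the bundled simulations), the
one-seed-per-cell derivation from the master seed, and |ρ| rather than a
t-transform as the mass statistic are package choices, each behind a
parameter.

## Determinism and numerical choices

One master seed drives everything; per-(subject, session, block) and
per-test-cell seeds are derived by a counter hash kept below 2^31, so any
single block can be regenerated in isolation and reruns are
bit-identical (the study's ground-truth sidecar and the results manifest
hash-verify this). EDF output uses 1 s records, 16-bit samples, and a
per-channel symmetric physical range written with the exact header
string used for scaling, so round-trips are exact to quantization.
Quantile type 7 (R's default) defines the 97.5th percentile; `round()`
half-to-even applies to the current-density reporting, with the nominal
disc area rounded to 3.14 cm² so the printed densities reproduce to three
decimals.

## Problem sizes used by the bundled validation

The test-suite simulations are sized for a single CPU: movement blocks of
12–20 trials and 30 s resting blocks for wavelet-level recovery; 12
cohorts of 8 subjects × 15 trials per cell for contrast-detection rates
(lmer-on-log backend); 60 small cohorts for the null rejection rate; 200
null datasets × 200 permutations for the familywise error measurement;
and 8 full 72-cell batteries (20 subjects, 12×15-pixel maps) for the
planted-association specificity check. These sizes are the package's
stated validation conditions; the defaults in `default_config()` (20
subjects, 60 trials, 3 min resting blocks, 1000 permutations) remain the
emulated protocol.

## Known limitations

* No artifact model (ocular, myogenic, vascular), no bad channels, no
  re-referencing: rejection and exclusion logic is exercised by injected
  amplitude spikes, not realistic artifact topographies.
* The generator's stationary sinusoids cannot express burst-like beta
  dynamics or frequency-dependent modulation depth; see the peak-frequency
  caveat above.
* Wavelet power and mixed-model effect sizes are validated on synthetic
  ground truth; nothing here calibrates against empirical cohort data.
* The CLI is a thin wrapper (`inst/scripts/run_pipeline.R`); the package
  functions are the primary interface.
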