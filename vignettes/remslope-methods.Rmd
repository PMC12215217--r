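---
title: "Aperiodic spectral dynamics of REM microstates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aperiodic spectral dynamics of REM microstates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remslope)
```

## The scientific question

REM sleep alternates between *phasic* periods — bursts of rapid eye
movements (EMs) with vivid, internally oriented experience — and *tonic*
periods of oculomotor quiescence with greater environmental
responsiveness. The broadband, non-oscillatory ("aperiodic" or
"fractal") component of the EEG power spectrum follows an approximate
power law $P(f) \propto f^{\alpha}$; its exponent $\alpha$ (equivalently
the slope of log-power against log-frequency) tracks arousal, sleep
depth and, in the gamma range, the cortical excitation–inhibition
balance. `remslope` implements a complete analysis chain asking (i)
whether the aperiodic slope differs between phasic and tonic REM, and
(ii) whether, within single REM episodes, fluctuations of aperiodic
activity lead or lag fluctuations of eye-movement intensity.

Three analysis surfaces are provided:

* a **binary** (epoched) pipeline — EOG-rule segmentation into
  phasic/tonic 4-s epochs, IRASA slope estimation, within-participant
  z-transform, paired contrasts, ROC/AUC, false-discovery control;
* a **continuous** epoch-level association between EM peak amplitude and
  slope (Spearman);
* a **within-episode** pipeline — lagged rank cross-correlation between
  the EM-amplitude and slope time series of individual REM episodes,
  pooled on the Fisher-z scale, with episode-centred effect sizes and a
  Bayesian estimate of the population prevalence of the effect.

## Spectral model and estimator

Each area-averaged EEG signal is analysed in consecutive 4-s epochs with
a single periodic Hann taper, giving a 0.25-Hz grid that places bins
exactly at the 2, 30 and 48 Hz band edges. Sub-windowed (Welch)
averaging within the epoch was rejected deliberately: the 2-Hz lower
edge of the low band needs several bins below 4 Hz, which a shorter
sub-window cannot supply.

**IRASA.** For every factor $h$ in $\{1.1, 1.15, \dots, 1.9\}$ the epoch
is resampled by $h$ and by $1/h$ and both spectra are evaluated on the
original grid; the geometric mean $\sqrt{P(hf)\,P(f/h)}$ leaves a power
law invariant while displacing narrowband peaks to $f/h$ and $fh$, and
the median across the factor set suppresses them. The fractal component
is that median; `oscillatory = total - fractal` bin-wise, exactly.
Resampling is done in the Fourier domain (spectrum truncation /
zero-padding), which is an ideal anti-aliasing low-pass: the expected
spectrum of shaped noise is then exact at every bin, and slope recovery
becomes an analytic property rather than an approximation of a
polyphase filter. Interpolation onto the analysis grid is linear in
log-log coordinates, where a power law is exactly linear.

**Slope fit.** Ordinary least squares of $\log_{10}$ fractal power on
$\log_{10}$ frequency over the in-band bins (edges inclusive), per
epoch; $r^2$ is exposed for quality control. Bands: low 2–30 Hz (the
sleep range, with < 2 Hz excluded because EM potentials extend over
0.3–2 Hz), a 5–30 Hz control band, and high 30–48 Hz (the
excitation–inhibition-sensitive range). Fits are per-epoch and then
averaged; fitting an epoch-averaged spectrum instead is possible but was
not made the default, because per-epoch fits keep the epoch as the unit
of analysis for the state comparison and the time-series analyses.

**A finite-sample property worth knowing.** With a single taper each
periodogram bin is $\chi^2_2$-distributed; the geometric mean of the two
independent resampled bins is therefore biased low by a constant factor
($\mathrm{E}[\sqrt{X}]^2 \approx 0.79$ of the mean, shrunk a little
further by the median across factors). The factor is
frequency-independent, so it cancels exactly in the log–log slope — the
quantity this package reports — while the `fractal` *level* sits some
25–35% below `total` even for a pure power law. No debiasing constant is
applied; the canonical implementations apply none either. Tests
therefore assert the slope fixed point, not per-bin equality.

## Segmentation rules

On each 2-s EOG window: an **EM** flag requires an excursion above
150 µV whose contiguous above-threshold extent is shorter than 500 ms
(the extent definition operationalizes "shorter than 500 ms", which has
no standard start/end convention); **quiescent** requires every
excursion below 25 µV; anything else is intermediate. A 4-s epoch is
*phasic* if both its subwindows are EM, *tonic* if both subwindows and
the flanking 2-s windows are quiescent (read symmetrically to the phasic
rule; windows beyond the recording edge count as quiescent), else
unclassified. Either EOG channel may satisfy the amplitude criterion —
conjugacy is checked upstream by the event detector, not re-checked
here. Finally, selected segments must lie at least 8 s apart; since the
source rules do not say which of two close segments survives, the
greedy earliest-first resolution was chosen and is asserted exactly in
the tests (every kept pair ≥ 8 s edge-to-edge).

## Eye-movement detection

Both EOG channels are zero-phase band-passed to 0.3–10 Hz. Candidate
events are excursions of the larger-channel envelope above 50 µV
(rolling-maximum smoothing over 0.25 s bridges the mid-event zero
crossing of a biphasic deflection); a candidate must be **anti-phase**
across the channels at its extremum — the conjugacy signature of a real
eye movement — and its duration (twice the half-period of the lobe
holding the extremum) must fall in 0.3–1.2 s with a dominant frequency
(reciprocal of twice the half-period) in 0.5–5 Hz. The per-epoch series
is the maximum absolute peak amplitude of the events whose extremum
falls in the epoch ("absolute peak amplitude" motivates max rather than
mean when events co-occur), with 0 for event-free epochs: keeping the
grid intact matters for cross-correlation, and the rank transform
absorbs the resulting ties as mid-ranks.

## Within-episode analysis

Episodes are maximal contiguous REM runs longer than 10 min — long
enough to contain several cycles of the ~2-min infra-slow EM bursting;
brief awakenings are not bridged. Both series are ranked once
(mid-ranks), then correlated over the overlapping portions at lags from
−300 to +300 s in 4-s steps (151 lags): ranking once follows the
described procedure, whereas re-ranking each overlap would change tie
behaviour (a `rerank` switch is provided). Sign convention: **a peak at
negative lag means the slope series leads** the eye movements.
Significance per lag uses the Fisher-z interval with the overlap length,
$|r| > \tanh(1.96/\sqrt{n_\ell - 3})$; a pooled mode using the full
series length for every lag (one flat threshold) is available because
the source analysis is ambiguous on this point. No correction across
the 151 lags is applied by default, as none is described for the
original analysis. Pooling across episodes averages z per lag (the
variance-stabilized scale) and maps back through `tanh`.

The episode-centred effect size is the fraction of episodes with a
significant correlation of the required sign in a lag window (default:
lag 0). Population prevalence: each episode is significant with
probability $\theta = \gamma + (1-\gamma)\alpha$, where $\gamma$ is the
prevalence of true effects and within-episode sensitivity is taken as 1
(the standard form of the method). With a uniform prior,
$\theta \sim \mathrm{Beta}(k+1,\,n-k+1)$; transformed to $\gamma$ and
truncated, the posterior mass below $\theta = \alpha$ becomes a point
mass at $\gamma = 0$. The MAP is the mode of the continuous truncated
density — it equals $\max(0, (k/n-\alpha)/(1-\alpha))$ up to the grid
step (5·10⁻⁴) — and the 96% highest-density interval accumulates cell
masses, the zero atom included.

## Cohort statistics

Per participant, epoch-level slopes of the four areas and both states
are merged into one vector per band and z-transformed before averaging
per (area, state): this removes device-dependent offset and scale while
preserving the within-participant structure (an affine-invariance test
guards this). Contrasts are two-tailed paired t-tests with paired
Cohen's d on difference scores ($\bar d / s_d$; the variant is stated
because several exist). AUC uses the Mann–Whitney rank identity with
half credit for ties, cross-checked against exhaustive pair counting;
the class with the larger mean is "positive", and sensitivity and
specificity are read at a single cutoff, the pooled median.
Benjamini–Hochberg step-up control is applied across the area-by-band
contrasts. The epoch-level amplitude–slope association includes only
epochs whose EM amplitude exceeds 50 µV and refuses to run below 10
epochs.

## The synthetic generator: what it emulates, and what not

Ground-truth testability drives the generator. EEG per area is shaped
Gaussian noise whose amplitude spectrum follows a broken power law
continuous at a 30-Hz knee — low-band exponent −2.10 tonic / −2.25
phasic, high-band −3.90 / −3.50. The tonic values and the signs of the
state differences follow the published group means for adult REM sleep
(low band near −2.1, high band near −3.9, phasic steeper in the low
band, flatter in the high band); the difference magnitudes
(Δlow = −0.15, Δhigh = +0.4) are generative choices inside the reported
ranges, since measured differences on human data are not generative
effect sizes. State switching crossfades two pre-generated streams over
0.5 s, avoiding broadband switching edges. Narrowband oscillations
(default: 7.5 Hz theta at 3 µV RMS) ride on top, exercising IRASA's
purpose.

EMs are scripted as a clustered point process: burst centers every
120 s (the infra-slow timescale of EM density) with ±20% jitter — a
strictly periodic process would put genuine cross-correlation side
lobes at multiples of ±120 s, an artifact of over-regularity rather
than a method property — each burst spanning 20 s (five 4-s epochs,
which is what produces the roughly balanced phasic/tonic epoch counts
reported for full-night data), with at least one event per 2-s
subwindow so that burst epochs satisfy the phasic rule by construction.
Amplitudes are log-normal (median 180 µV, σ_log 0.3) truncated at
150 µV; durations are uniform in 0.3–0.5 s, satisfying at once the
segmentation constraint (above-threshold extent < 500 ms) and the
detector's duration band (0.3–1.2 s) — scripting shorter events would
manufacture misses the detector is blind to by design. Events are
rendered as one anti-phase biphasic sine cycle per event on the two EOG
channels over 5-µV Gaussian background, which keeps tonic windows under
the 25-µV bound with margin. A per-participant baseline shift of all
exponents (SD 0.1) models stable individual differences; the value is a
package choice — published per-state dispersions (~0.3–0.7) mix
between-participant and epoch-level measurement variance and cannot be
read as a baseline SD.

The generator does **not** emulate realistic sleep architecture
(spindles, K-complexes, NREM staging), sawtooth-wave morphology, EMG/ECG,
oculomotor artifacts leaking into the EEG, or scorer disagreement.
Passing tests therefore demonstrate correctness of the estimators and
rules under known ground truth — not robustness to everything real
recordings contain.

## Numerical choices and degenerate inputs

* Band edges inclusive on the discrete grid; 4-s epochs put bins exactly
  at 2, 30, 48 Hz.
* Epochs with non-finite samples or zero variance yield `NA` slopes —
  never a silent zero.
* `fit_aperiodic_slope` distinguishes "too few bins" from "non-positive
  fractal power" (a numerical failure of the decomposition).
* A zero signal has an all-zero periodogram; non-finite input errors.
* Identical pairs in `paired_contrast` return t = 0, d = 0, p = 1;
  constant non-zero differences are an error.
* All randomness flows through explicit integer seeds (generator
  functions restore the ambient RNG state); analysis stages are
  seed-free and byte-deterministic.
* EDF export quantizes to 16 bits over per-channel symmetric integer
  bounds; round-trip error is below 0.05 µV for physiological ranges.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script scale the study down to run on
one CPU: exponent recovery uses 600-s realizations (150 epochs) per
exponent; oscillation rejection 240 s; segmentation and detection one
720-s episode; the cohort analysis 12 participants with 1200 s of REM
each (roughly 20 kept phasic and 45 kept tonic epochs per participant —
full-night recordings would provide about five times more); lag
recovery 12 coupled episodes of 160 epochs; the null calibration 200
Monte-Carlo pairs of length 250; the prevalence oracle all
$k \le n \le 100$; the AUC oracle 1000 random instances.

## Known limitations

* The high-band (30–48 Hz) slope rests on 0.2 decades of frequency; its
  per-epoch variance is intrinsically large, which is why state
  discrimination is evaluated on per-participant state means.
* Where the spectrum changes regime — the 30-Hz knee of the synthetic
  broken power law, or any real spectral knee — the IRASA geometric mean
  evaluates the spectrum at $hf$ and $f/h$ across the knee, pulling the
  fitted slopes of the two bands toward each other (on the shipped
  generator, roughly −2.3/−3.2 recovered from −2.1/−3.9 generative, with
  the state *differences* compressed but preserved in sign). Single-regime
  power laws are recovered without bias; knee-adjacent fits inherit this
  mixing, which is a property of the method itself.
* The 8-s separation rule thins long uniform runs aggressively (one
  epoch kept per 12 s); this mirrors the scoring rule, not a package
  preference.
* Prevalence assumes within-episode sensitivity of 1; with weak
  per-episode power the MAP underestimates the true prevalence.
* The EDF reader covers one-rate, uV-scaled files of the kind the
  package writes; it is not a general clinical EDF+ parser.
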