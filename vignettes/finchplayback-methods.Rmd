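---
title: "Models and methods behind finchplayback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind finchplayback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finchplayback)
```

# The scientific problem

Zebra finches exchange short vocalisations constantly; the pair answers
each other's calls within fractions of a second. If a soft unlearned call
carries the caller's identity, a listening bird can address its mate in a
vocalising crowd by answering the right call quickly. The playback design
this package implements probes exactly that: a focal bird hears series of
calls from three individuals of the opposite sex differing in familiarity
— its mate (`m`), a familiar bird (`f`) and an unfamiliar bird (`uf`) —
and recognition is inferred when the number or latency of the vocal
answers differs by familiarity.

The package covers the full workflow: extracting and typing calls from
audio, building the playback schedule, scoring answers, fitting mixed
models with posterior-simulation uncertainty, and quantifying how
individually distinct each call type is. A seeded synthetic-data
generator stands in for real recordings so that every stage can be
validated against planted ground truth.

# The synthetic generator

## Waveforms

`generate_call_waveform()` synthesises a call as a harmonic stack: a
fundamental $f_0$ (call-type base plus an individual offset) with $H$
harmonics whose amplitudes roll off geometrically (ratio 0.6), plus a
white-noise floor band-limited above 400 Hz. The harmonic part is scaled
to $1 - \text{noise floor}$ so peak amplitude never exceeds 1. Two
choices deserve a note:

* **Geometric roll-off** keeps closed-form expectations for the spectral
  features (the spectral centroid and first-peak fundamental of a stack
  are known), so feature extractors can be tested against planted
  parameters rather than against themselves.
* **Band-limited noise.** Real zebra finch calls carry essentially no
  energy below a few hundred hertz, and recording chains high-pass their
  input. Full-band white noise would additionally make the stimulus
  high-pass non-idempotent (every pass would keep shaving the transition
  band), so the generator reflects the realistic band limit.

The default repertoire spans the soft calls, the distance call and song,
with distinct fundamentals (450–1200 Hz), durations (0.07–0.8 s) and
harmonic counts per type; distinct per-bird fundamental offsets make
individuals separable by exactly the features the distinctiveness module
uses.

## Exchange and response streams

`generate_exchange_session()` models baseline pair calling: each bird
calls spontaneously as a homogeneous Poisson process per call type
(default 0.05 events/s per type, giving a few thousand events over a
four-hour scored session). After each spontaneous call the partner
answers with probability `answer_prob`, at a lag drawn from a normal
distribution truncated to the latency analysis window $(0, 1.5]$ s;
answers do not trigger answers. Real calling is burstier than Poisson —
this is a deliberate simplification adequate for validating scoring and
models, and it is stated in the configuration rather than hidden.

`generate_playback_responses()` applies the same answer model per
scheduled emission, with familiarity-dependent probability and latency.
Defaults plant the effects the analysis is designed to detect, at the
scale of the clearest published contrasts for this paradigm: answer
probability 0.57 (mate) versus 0.23 (non-mate), latency means 0.55 s
versus 0.67 s. The latency SD is 0.2 s: the ~0.4 s spreads seen in raw
data pool between-bird and between-series variance, whereas this
parameter is the within-series residual; 0.2 s keeps the truncation at
$(0, 1.5]$ mild (the 0 bound sits 2.75 SDs below the mate mean). Answer
call types follow the observed composition (stack-dominated: 69.2% of
female answers, 50.1% of male answers).

Where planted values are compared with estimates, the truth is the
**truncated**-normal expectation computed by numerical integration
(`truncnorm_expectation()`), not the untruncated mean — on the default
scale the planted 0.12 s contrast realises as 0.1185 s.

## Reproducibility

Every operation draws from its own RNG stream seeded by
`split_seed(master_seed, "stage/key")`, a multiplicative hash reduced
modulo $2^{31}-1$. The same `sim_config()` therefore reproduces
byte-identical outputs, and any stage can be regenerated in isolation.

# Acoustic analysis

Segmentation emulates threshold-based call extraction: a 2 ms
moving-average envelope of $|x|$, maximal runs at or above the threshold,
merging of runs separated by less than 20 ms, and discarding of runs
shorter than 10 ms. The threshold is in envelope units and is the user's
choice, as it was a manual setting in the original workflow.

Spectral analysis uses a Hann window of 512 samples with 50% overlap
(~86 Hz bins, ~5.8 ms hops at 44.1 kHz) — configurable; published
descriptions of this workflow do not fix the FFT parameters, so these
defaults are our own and are stated rather than claimed historical.
Choices that the source software left undefined:

* **Fundamental ("first peak")**: the lowest local maximum of the power
  spectrum above the 85 Hz high-pass edge whose height exceeds 5% of the
  spectral peak; a cepstral alternative is available via
  `estimate_fundamental(method = "cepstrum")`.
* **Modal frequency**: the most frequent per-window peak bin across the
  segment's analysis windows.
* **Wiener entropy** is reported on the linear $[0,1]$ scale (geometric
  over arithmetic mean of power bins): 1 for a flat spectrum, 0 when any
  bin is exactly zero, scale-invariant, with closed-form test values
  (e.g. bins $(1,2,4) \mapsto 6/7$). A log-scale flag exists for
  compatibility with dB-style definitions.

The 14-feature sonogram set treats the time-averaged, sum-normalised
power spectrum as a probability distribution over frequency: mean and SD,
median, skew, kurtosis, spectral flatness, normalised Shannon entropy,
mode, the precision of the mean-frequency estimate across windows, peak
frequency of the max-hold spectrum, first-peak fundamental, dominant
frequency (mean per-window peak) and its maximum, and duration.

`cluster_calls()` z-scores features, drops zero-variance columns, runs
k-means with 10 restarts (k is user-supplied: the repertoire size is
known), and flags segments as `NOISE` only when their distance to the
nearest centroid exceeds **both** the 99th percentile of distances and
the mean + 3 SD. A bare percentile rule would always flag ~1% of
segments, including in perfectly clean data; the conjunction makes noise
flagging conservative while still catching genuine outliers. Manual
refinements enter through an explicit edits table
(`manual_edits = data.frame(segment_id, label)`), replacing interactive
cluster correction.

# Playback design

`build_schedule()` reproduces the trial structure exactly: one block per
call type in the subject's roster (males hear 5 female call types = 15
series; females additionally hear song = 18 series), three series per
block (one per familiarity), 300 emissions per series (3 exemplars × 100
repeats, shuffled), inter-call intervals uniform on $2 \pm 0.5$ s,
inter-series silences $70 \pm 10$ s, inter-block silences $130 \pm 10$ s.
Block order, familiarity order within blocks, and emission order are
unconstrained uniform permutations from the seed — the original
"semi-random" ordering rule is not documented, so no extra constraint is
invented. Loudspeaker calibration (50–74 dB SPL by call type) is a
hardware concern outside the schedule's scope.

`preprocess_stimulus()` applies the stimulus chain: raised-cosine fades,
85 Hz 4th-order Butterworth high-pass run forward and backward
(zero-phase; the input is zero-padded by 8 cutoff periods because plain
`filtfilt` edge transients at an 85 Hz edge extend over hundreds of
samples), a second fade pass to cap any residual filter transient, and
peak normalisation to −0.1 dBFS ("normalised to 0.1 dB (maximal sample
value)" is read as a −0.1 dBFS peak ceiling; the ceiling is
configurable). Fading *before* filtering matters: an abrupt call edge
splatters energy below the cutoff, and a filter-then-fade order would
re-create sub-cutoff content on every application. Fades are implemented
as an envelope cap — gain $\min(1, \mathrm{cap}(t)/\text{running
max}|x|)$ with the cap scaled to the signal's own peak and iterated to a
fixed point — which is scale-invariant and a no-op on already-faded
edges. The result is that the whole chain is idempotent (re-running it
changes a processed stimulus by less than $10^{-3}$ relative), a
property the test suite checks across the synthetic repertoire. Fade
length defaults to 5 ms (undocumented in the source workflow).

# Answer scoring

`detect_answers()` implements the answer rule: a responder event answers
a trigger when its onset lies in $(t, t + 0.5]$ after the trigger onset,
measured onset-to-onset. A responder event answers at most one trigger —
the nearest preceding one — while a trigger may collect several answers.
The window is open at 0 (a simultaneous call is not an answer) and closed
at the boundary; whether the historical rule was open or closed at
exactly 0.5 s is not documented, so the closed choice is stated here.
`first_answer_latency()` uses the wider 0–1.5 s window of the latency
analysis. Scoring is verified against a quadratic brute-force oracle on
random streams.

`repeatability_index()` computes one-way ANOVA mean squares by group
(pair). The primary index is the intraclass correlation
$r = (MS_A - MS_W) / (MS_A + (n_0 - 1) MS_W)$, clamped to $[0,1]$, with
the raw F ratio $MS_A/MS_W$ reported alongside: descriptions of this
analysis say "F ratio" while the cited index and the published values
near 0.995 imply the bounded ICC form, so both are exposed and the
bounded one is primary.

# Inference

The response models are linear mixed models on square-root-transformed
responses — the latency of the first answer per emission, or the answer
count per series — with familiarity × call type × trial (all
interactions) as fixed effects and random intercepts for subject,
audience and playback order. The structure is design-based, not
selected: a random effect whose variance estimates to zero stays in the
model (the fit warns with the variance components rather than failing).
Fits use maximum likelihood, as interest centres on the fixed effects.
Factors with fewer than two observed levels are dropped so reduced
designs (one call type, one trial) fit naturally. Latency rows exist
only for emissions that received an answer — a missing latency is
missing, not zero — while counts of zero are valid data.

"Bayesian" here means posterior simulation under flat priors:
`simulate_posterior()` draws 10 000 coefficient vectors from the
asymptotic joint posterior $N(\hat\beta, \widehat{\mathrm{Cov}})$ of the
fixed effects and maps each draw to every fixed-effect cell mean. This is
the standard `sim`-style procedure, not MCMC; no prior tuning is
involved. Per cell we report the fitted value and the 2.5/50/97.5
percentiles; per comparison, the exceedance probability
$p = \Pr(\text{cell}_1 > \text{cell}_2)$ across paired draws, with ties
(within $10^{-9}$ of the draw scale) counted one half. The two-step
significance rule is: non-overlapping credible intervals, otherwise
$p < 0.05$ (first cell smaller) or $p > 0.95$ (first cell larger). The
directional rule has 5% type-I error by construction; the calibration
study (`null_calibration_study()`) verifies this empirically at reduced
scale — 500 replicates of a reduced trial (10 repeats per exemplar, one
subject) with no familiarity effect planted. No multiple-testing
correction is applied anywhere, matching the analysis this reimplements;
all comparisons are reported with raw exceedance probabilities. When a
fit is exactly deterministic (zero residual variance), the coefficient
covariance is not computable and the posterior degenerates to a point
mass at the estimates.

Secondary analyses follow the same pattern. `habituation_test()` bins
calls into 500 s bins (roughly one series), fits counts on bin (factor)
with a subject random intercept, and compares first versus last bin by
posterior simulation. `answer_type_composition_test()` runs a
Kruskal–Wallis rank-sum test across the three familiarity levels, only
when at least 8 non-null values are available.
`baseline_playback_correlation()` regresses playback answer proportions
on baseline proportions (for combinations passing the ≥ 3-call and
repeatability screens) with a posterior-simulated slope interval.
`subset_robustness()` re-runs scoring and modelling on the first and
last 30 emissions of each series and tabulates sign agreement of the
mate-versus-nonmate contrasts against the full-series analysis; series
shorter than the subset are used whole and flagged. Playback-order
random intercepts are crossed with subject, not nested — the design
leaves this open, and crossing is the weaker assumption.

# Individual distinctiveness

`distinctiveness_index()` standardises the 14 features, runs PCA on the
correlation matrix (features mix Hz, seconds and unitless measures, so
covariance PCA would let high-variance features dominate), keeps the
first two components, fits an LDA on caller identity, and predicts the
training calls themselves. The proportion of incorrect assignments is
the (inverse) distinctiveness index. Resubstitution is the default
because the procedure this mirrors predicted the same calls used for
fitting; leave-one-out is available (`method = "leave_one_out"`), and a
property test checks the expected optimism ordering between the two. In
the experimental design each focal bird contributes 9 stimuli per call
type (3 exemplars × 3 identities), and "familiarity level" is a proxy
for caller identity — one individual per level per focal bird; the
labels are kept as identities, not relabelled. For $k$ balanced
indistinguishable classes the chance misassignment is $(k-1)/k$;
resubstitution sits below that for small samples (optimism), which is
why the chance-level validation pools 30 stimuli per identity.
`relate_distinctiveness_to_response()` then regresses response magnitude
(answer-count or mean-latency difference, mate minus familiar/unfamiliar,
latencies averaged per individual before differencing) on the index with
a subject random intercept.

# Validation studies and problem sizes

The acceptance-level studies are sized to run comfortably on one CPU:

* Null calibration: 500 replicates of a reduced trial (10 repeats per
  exemplar), 4 000 posterior draws each (~20 s).
* Effect recovery: 200 replicates at experiment scale for the latency
  contrast — 300 emissions per series, one call-type block, 6 subjects —
  2 000 draws each (~40 s). Power for the planted 0.12 s contrast is
  effectively 1, and the mean recovered difference matches the
  truncated-normal truth within Monte-Carlo error.
* Clustering recovery: 20 replicates of 3 call types × 8 synthetic
  exemplars, scored by adjusted Rand index against generating labels.
* Distinctiveness extremes: one pooled chance-level set (3 × 30 identical
  calls) and one separated set (3 identities, 300 Hz fundamental steps).

# What the synthetic validation does and does not show

The generator emulates the *structure* of the experiment — design counts,
timing, answer windows, familiarity effects of realistic size — but not
every property of real data: calling is Poisson rather than bursty,
latencies are truncated-normal rather than skewed, waveforms are
stationary harmonic stacks without frequency modulation, and there are
no overlapping vocalisations, no audience calls bleeding into the focal
channel, and no measurement noise in event times. Passing tests
therefore demonstrate that the pipeline is *correct* (it recovers what
was planted, at the right error rates), not that any particular
biological conclusion holds; conclusions about real birds require real
recordings. The numerical results published for this paradigm derive
from recordings not bundled here and are not reproduced by this package.

# Known limitations

* The mixed models assume Gaussian residuals on the square-root scale;
  the fit records normality and heteroscedasticity diagnostics but does
  not act on them.
* With familiarity varying only between series, series-level random
  intercepts absorb part of the familiarity information; at the design's
  series counts this is the intended conservatism of the original
  structure, but users fitting reduced designs should keep an eye on
  singular-fit warnings.
* The posterior simulation is asymptotic; with very few subjects the
  intervals can undercover slightly (the coverage test allows for this).
* WAV support is mono 16-bit PCM only.
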