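---
title: "Audiovisual phoneme representations and directed information flow in auditory-cortex ECoG: methods"
author: "stgflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audiovisual phoneme representations and directed information flow in auditory-cortex ECoG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During audiovisual speech, the sight of a talker's mouth can change what a
listener *hears*: in the McGurk illusion, a video articulating one phoneme
paired with audio of another makes most listeners report the video's
identity. stgflow implements an analysis chain for trial-structured
multi-electrode field-potential recordings (ECoG) from auditory cortex in a
four-alternative audiovisual phoneme task, asking two questions:

1. Do high-gamma (75–200 Hz) representations on superior-temporal-gyrus
   (STG) electrodes follow the video or the audio identity on illusion
   trials?
2. Does information about stimulus identity move in the caudal-to-rostral
   direction along the STG as the trial unfolds?

Because no patient recordings are distributed, the package ships a
first-class synthetic-data generator with known ground truth; every claim
the pipeline makes is validated as parameter recovery against that
generator.

## Task structure and timing conventions

All times are in seconds relative to audio onset. Each trial shows video
from −1 s (mouth articulation begins), plays a 500 ms audio phoneme at 0 s,
and continues for 1 s after audio offset; epochs cover [−2, +1.5] s so that
a stimulus-free pre-video baseline ([−2, −1] s) is available. Four video and
four audio phonemes (BA, GA, VA, THA) are crossed into 16 combinations.
Three one-second analysis intervals are used throughout: *baseline*
([−2, −1] s), *video-only* ([−1, 0] s) and *audio+video* ([0, 1] s).

## The synthetic-data generator

`simulate_dataset(sim_config())` produces per-trial voltage epochs
(time × electrode, µV-scaled) containing:

* **Background**: independent 1/f-amplitude-shaped Gaussian noise per
  electrode, unit SD — the canonical broadband statistics of field
  potentials.
* **Phoneme codes**: one fixed random spectro-temporal template per phoneme
  (six Gabor-like components with random frequency 80–195 Hz, time center,
  width and amplitude, drawn once per seed), active from video onset to
  phoneme offset. Carrier *phases are re-drawn every trial*: high-gamma
  activity is not phase-locked, so identity information lives in
  spectro-temporal power, not the raw waveform. A mild log-normal
  trial gain (σ = 0.2) adds amplitude variability. The template identity
  follows the video or the audio stimulus per `code_carrier`.
* **Shared coding sites**: the template is injected at equal amplitude on
  all three designated electrodes (posterior, middle, anterior). This is a
  deliberate design choice: the tendency statistic below reduces by the
  chain rule to the difference of the two electrodes' marginal stimulus
  informations, so directional effects are identifiable only relative to a
  symmetric baseline. Equal baseline coding makes "no coupling" map to "no
  tendency", and coupling map to a positive tendency toward the
  destination.
* **Coupling**: during `coupling_interval` the destination electrode
  additionally receives a coherent copy of the source's single-trial burst,
  delayed by `coupling_lag` (50 ms) and scaled by `coupling_gain` (1.0).
  The destination thereby becomes the better-decoded site in that interval
  — the planted signature of directed transfer.
* **Evoked response**: a phoneme-unspecific audio-onset-locked burst on the
  three coding electrodes, giving electrode selection its 75–200 Hz
  criterion signal without adding identity information. Its amplitude
  (`evoked_snr`, default 0.5) is parameterized separately from the pattern
  because evoked responses dominate stimulus-locked power in auditory
  cortex; this is what makes power-based electrode selection far more
  sensitive than single-trial decoding, as in real recordings.
* **Behavior**: congruent trials are answered correctly with probability
  0.75 (errors uniform over the other three labels); incongruent trials
  report the video identity with probability `mcgurk_prob` (default 0.8),
  otherwise mostly the audio identity with a 10% lapse spread over the two
  remaining labels.

**Default operating point.** `snr = 0.12` (burst RMS relative to the unit
background SD) was chosen so that single-electrode, single-interval pairwise
decoding sits mid-range between chance and ceiling (posterior ≈ 0.8,
coupled middle ≈ 0.95 in the video-only interval). This matters twice over:
at ceiling all electrodes decode perfectly and every information difference
collapses to zero; at chance nothing is recoverable. `mcgurk_prob = 0.8`
makes ≥ 90% of incongruent combinations pass the per-combination binomial
criterion at 10 trials each, so the McGurk category is well populated.
Default trial counts (10 per combination, 160 total) mirror a single
session of the task.

**What the generator does not emulate**: cross-electrode correlated noise,
line noise and artifacts, non-stationary background, epileptiform activity,
latency jitter of the evoked response, and electrode-position geometry.
Passing recovery tests therefore demonstrates the *correctness of the
estimators under the stated model*, not robustness to every pathology of
clinical recordings.

## Preprocessing

Recordings above the 1 kHz analysis rate are low-pass filtered at 500 Hz
with a zero-phase (forward–backward) FIR filter and decimated; the
anti-alias filter always precedes decimation. Zero-phase filtering is
essential because the information-transfer analysis is latency-sensitive; a
causal filter's group delay would bias burst timing. The filter order
(`max(48, 2·ceil(3.3·fs/cutoff))`, Hamming-windowed) meets a ≥ 40 dB
stopband and ≤ 1% passband error after the two passes. Common-average
re-referencing subtracts the cross-electrode mean per time sample (per
hemisphere when labels are provided); it is exactly idempotent and requires
at least two electrodes per group.

## Multitaper spectrograms

`multitaper_spectrogram()` uses a 500 ms moving window with 10 ms step
(50 ms in the decoding feature path, where the 500 ms window makes finer
steps redundant) and Slepian tapers with time–bandwidth product NW = 7 and
K = 11 leading tapers (K ≤ 2NW − 1). The tapers are computed from the
standard symmetric-tridiagonal eigenproblem and verified in the test suite
against frozen reference values from an independent implementation. Power
is one-sided spectral density scaled so its frequency integral equals the
signal variance; only windows fully inside the epoch are used (no padding),
and window centers define the time axis — this keeps the [−1, 1] s
difference statistic free of edge artifacts.

Per-band normalization (`normalize_by_band()`) z-scores each frequency row
against its mean and SD over the pre-video baseline (t ≤ −1 s), the only
stimulus-free segment. A frequency band that is constant everywhere
normalizes to zero; a band with zero baseline variance but later deviation
is an error, because its z-units would be undefined.

The difference-spectrogram statistic is the mean of |A − B| over all
time–frequency cells in [−1, 1] s of two trial-averaged, normalized
spectrograms. For each McGurk combination (video V, audio A) it is computed
against the matched condition with the same video (V&V) and the one with
the same audio (A&A); a video-driven code makes the same-video difference
smaller, and the per-electrode × combination statistics are compared with a
two-sided Mann-Whitney U test.

## Behavioral categorization and electrode selection

Incongruent stimulus combinations are labeled *McGurk* when the video
identity is reported more often than chance and *unmatched* when the audio
identity is; "more often than chance" is operationalized as a one-sided
exact binomial test against 0.25 (four-alternative task) at α = 0.05, the
minimal-assumption choice at per-combination sample sizes. Combinations
meeting neither criterion are *unclassified* and excluded from category
analyses; combinations meeting both are resolved by the larger report
fraction, with exact ties falling to unmatched (the non-illusory reading).

Electrode selection ranks electrodes by trial-averaged mean 75–200 Hz power
during the 1 s audio window, breaking ties toward the lower index, and
optionally restricted to an STG metadata flag (the simulation stand-in for
anatomical localization). Of the three selected electrodes the *middle*
(primary-auditory-proximal) one is identified by the generator's metadata
when available, otherwise physiologically as the site with the largest mean
evoked potential in [0, 0.4] s.

## Decoding

Features per trial concatenate, for each selected electrode, the raw
voltage trace and the unwrapped 75–200 Hz spectrogram cells over the
feature window (video onset to phoneme offset, −1 to +0.5 s). Per
cross-validation fold, columns are z-scored with training-half statistics,
projected onto the training half's leading principal components (minimal
number reaching ≥ 95% cumulative variance), and classified with a
two-class linear discriminant using the pooled covariance, equal priors and
ridge shrinkage (λ = 0.1) toward the scaled identity — with far more
features than trials some regularization is required for a stable solve.
Folds are stratified by label and seeded; all transforms are train-only
(a dedicated test perturbs held-out rows and asserts the training-side
transform is bit-identical).

Two analyses sit on top:

* `decode_stimulus_identity()` trains and tests under the chosen attribute's
  labeling for every unordered label pair (chance 50%). Incongruent designs
  carry a structural confound — video and audio identity never coincide —
  so a purely video-driven code would let audio labels be predicted above
  chance. The default `"balanced"` scheme subsamples each pair so the
  non-target attribute is identically distributed across the two classes,
  removing the confound; `"all"` and `"within_pair"` are available
  explicitly.
* `decode_mcgurk_identity()` asks the headline question directly: it trains
  each pairwise discriminant on *matched* trials (where the phoneme
  identity of the pattern is unambiguous) and applies it to the reciprocal
  McGurk trials of the pair, scoring each prediction against the video and
  the audio labeling. On reciprocal trials the two scorings are
  complementary, so a video-driven representation shows video accuracy
  above 50% and audio accuracy below 50% — the classifier "consistently
  picks the wrong auditory identity" — and an audio-driven code reverses
  the pattern.

## Information flow

From two electrodes' pairwise confusion tables the joint distribution over
(stimulus S, decoded response R_x, decoded response R_y) is assembled as
p(s)·p(r_x|s)·p(r_y|s): per-electrode conditionals are row-normalized
confusion counts, the prior defaults to empirical label frequencies, and
the electrodes are taken conditionally independent given the stimulus —
the only structure identifiable from per-electrode tables. A paired
per-trial variant (`joint_from_predictions()`) is provided for synthetic
data. Conditional mutual information is computed in bits (base-2 logs,
0·log 0 ≡ 0, no pseudocounts by default; additive smoothing is available
for very small counts).

The *information tendency* of an edge is
I(S;R_dest|R_source) − I(S;R_source|R_dest); positive values mean net
transfer toward the destination, and with edges ordered
posterior→middle and middle→anterior positive is caudal-to-rostral. By the
chain rule this difference equals I(S;R_dest) − I(S;R_source), which guides
both the generator design (above) and the choice of null: the sign-flip
permutation (random exchange of the two electrodes within each edge and
label pair) tests directional symmetry while preserving each electrode's
information content, and is the default in `tendency_null_band()`. A
label-permutation null (no stimulus information at all) is also available;
it is stricter but narrower than the sampling noise of tendencies between
two informative electrodes, and so answers a different question. Bands are
pooled min–max over all interval × edge × attribute conditions and
permutations (a max-statistic band controlling the familywise rate).
Refitting classifiers per permutation would be the gold standard; the
implemented null permutes against the stored held-out predictions, which is
exact under label exchangeability and keeps 200-permutation bands
affordable.

`interval_analysis()` recomputes features and classifiers independently per
one-second interval (windows are interval-limited by their centers; a 500 ms
window therefore smears ±250 ms across interval edges, which slightly leaks
adjacent-interval signal but treats all electrodes identically). Per-pair
tendencies are the replicates; the summary reports their mean.

## Hypothesis tests

Behavioral performance is tested with a one-way ANOVA of per-trial
correctness across categories plus Tukey-Kramer pairwise contrasts;
difference-spectrogram statistics with a two-sided Mann-Whitney U; decoding
accuracies with a one-sample Wilcoxon signed-rank against the 50% chance
median (degenerate all-at-chance input reports p = 1). Tests are two-sided
by default and use exact small-sample distributions where the base
implementations permit. Calibration suites in the tests check empirical
type-I rates at nominal α = 0.05 over 500 null replicates each.

## Numerical choices and degenerate inputs

* Slepian tapers: dense symmetric eigendecomposition, cached per
  (length, NW, K); sign convention fixed (positive mean / positive leading
  lobe).
* PCA components with singular values below `max(d)·1e-12` are never
  retained; zero-variance feature columns are dropped per training fold and
  counted.
* Confusion-derived joints reject any stimulus row with zero trials, and
  mismatched label sets or trial counts are errors, not warnings.
* CMI is clamped at 0 against floating-point underflow (the quantity is
  provably non-negative).
* Ties in electrode selection break toward the lower index, making runs
  reproducible.

## Problem sizes

The shipped analyses and tests use the generator defaults (160 trials,
8 electrodes, 1 kHz, 3.5 s epochs), 20 simulation replicates for recovery
claims, 100 label permutations for chance calibration, 200 permutations for
null bands, and 500 replicates for test calibration. These sizes were
chosen so each claim is measured with comfortable Monte-Carlo margins while
a full run of the suite stays desk-scale.

## Known limitations

* The conditional-independence joint cannot capture noise correlations
  between electrodes; genuinely redundant or synergistic coding across
  sites would need the paired per-trial variant.
* The tendency statistic is a difference of marginal informations; it
  cannot distinguish "transfer" from any other mechanism that makes one
  site more informative than the other in an interval.
* Common-average referencing redistributes shared signal: when a large
  fraction of the grid carries the coding signal (more than about half),
  the subtraction injects enough of it into quiet channels to invert the
  power ranking used for electrode selection. Real grids (48–64
  electrodes) and the 8-electrode default are safely below that regime;
  very small simulated grids are not.
* With 10 trials per combination the exact binomial categorization has
  limited power; combinations with borderline illusion rates land in
  `unclassified`.
* The 500 ms analysis window limits effective temporal resolution of the
  interval analysis; intervals shorter than ~0.75 s would be mostly window
  overlap.
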