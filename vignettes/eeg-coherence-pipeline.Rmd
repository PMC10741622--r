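---
title: "Methods: band coherence analysis of oral-exam EEG"
author: "examEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band coherence analysis of oral-exam EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(examEEG)
```

## The experiment this package models

A participant wearing a 14-channel wireless headset (10-20 positions AF3,
F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8, AF4; 256 Hz; passband
0.2–45 Hz) sits a simulated oral board examination. Event markers delimit
four segments: a 3-minute eyes-open baseline, 3 minutes reading a clinical
vignette, 12 minutes of questioning on that case ("answer 1"), and 3
minutes on a new case presented cold ("answer 2"). Behavioral measures are
a weighted 3-point observational checklist (two independent raters) and the
six NASA-TLX workload subscales. Participants belong to one of two
expertise groups, novice or experienced.

The analysis asks where spectral power and, more importantly, between-channel
synchrony differ between groups during each exam phase, and how far those
features explain observed performance and reported cognitive load.

## Feature model

Each task segment is split into non-overlapping 1-second epochs.
Epochs are rectangular at this stage; windowing belongs to the spectral
step. Epochs in which any channel deviates more than 100 µV from its epoch
mean, spans more than 200 µV peak-to-peak, or flatlines below 0.1 µV
peak-to-peak are discarded. These defaults are standard quantitative-EEG
practice for wet-electrode consumer headsets; they catch the generator's
movement-like transients while leaving its background untouched. Decisions
use only the epoch's own samples, so the artifact mask is equivariant under
epoch reordering, and stricter thresholds can only grow it.

From the retained epochs of a segment we compute, per frequency bin
$f \in \{0, 1, \dots, 128\}$ Hz:

* **PSD** — one-sided Kaiser-windowed periodograms averaged over epochs, in
  µV²/Hz, with the window power divided out so white noise of variance
  $\sigma^2$ integrates to $\sigma^2$;
* **magnitude-squared coherence** for every one of the
  $\binom{14}{2} = 91$ channel pairs,
  $$\gamma^2_{xy}(f) =
    \frac{\left|\sum_k X_k(f)\,\overline{Y_k(f)}\right|^2}
         {\sum_k |X_k(f)|^2 \cdot \sum_k |Y_k(f)|^2},$$
  the Welch estimator with zero overlap, the sum running over retained
  epochs $k$.

Band values are unweighted bin means over delta 1–3, theta 4–7, alpha 8–12,
beta 13–30 and gamma 31–45 Hz. The gamma band is capped at 45 Hz by the
acquisition passband; its lower edge sits one bin above beta so the bands
partition the 1 Hz grid. Delta is computed but excluded from default group
reports. With $L$ averaged epochs the coherence of two independent signals
has expectation $\approx 1/L$, not 0 — the well-known small-sample floor —
so a 180-epoch segment bottoms out near 0.0056.

Two further stages make features comparable across people:

1. **baseline correction** — the participant's eyes-open value of the same
   feature (same band, kind, channels) is subtracted from each task value.
   We correct in feature space, i.e. after band aggregation. An
   amplitude-space reading (subtract baseline amplitudes from the raw
   signal first) is possible in principle, but subtracting a per-channel
   mean amplitude leaves band power above 0 Hz and coherence unchanged, so
   for these features the readings collapse; feature-space subtraction is
   what the package implements.
2. **min-max normalization** — each feature column is mapped onto [0, 1]
   across the pooled 16 participants (per task and band; a constant column
   becomes zeros with a warning). Normalization is affine per feature, so
   group t statistics are unchanged by it.

## Statistics

Group contrasts use the independent-samples t-test, pooled-variance by
default: recomputing the published coherence table's p-values from its
printed means and SDs reproduces them under pooled df = 14, which
identifies the pooled variant as the faithful default; Welch is available
by argument. No multiplicity correction is applied by default, matching the
exploratory design; Benjamini–Hochberg is available by flag.
`ttestFromSummary()` applies the same formulas to printed summary
statistics, and agrees exactly with the raw-data test applied to the same
summaries.

Inter-rater reliability is the single-rater, absolute-agreement intraclass
correlation from the two-way random-effects ANOVA (ICC(2,1)): with $n$
subjects and $k$ raters,
$$\mathrm{ICC} = \frac{MS_R - MS_E}
  {MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$
reported with $F = MS_R/MS_E$ on $(n-1, (n-1)(k-1))$ degrees of freedom and
the standard F-based confidence interval (Satterthwaite denominator df).
The single-rater form is the one whose df pair (15, 15) matches a 16-subject,
2-rater design.

Outcome models (performance; TLX fraction) are built in three steps:
Pearson screening of candidate features at $\alpha = 0.05$; the Lasso over a
log-spaced 100-point lambda grid from $\lambda_{max}$ (smallest penalty
zeroing all coefficients) down to $10^{-4}\lambda_{max}$, with the penalty
chosen by 5-fold cross-validation at the minimum mean MSE (plain random
folds, seeded — at n = 16 stratification would be moot); and an ordinary
least-squares refit on the selected variables. The refit's standard errors
and p-values are *naive*: they ignore the selection step, which is how such
tables are conventionally reported, and they should be read as descriptive.
Predictors are standardized internally before penalization.

A note on "support recovery": at n = 16 the minimum-MSE lambda
systematically over-selects — it reliably *contains* the true support but
rarely equals it exactly, even at high signal-to-noise (this is the Lasso's
screening property, and it is why the tests and the acceptance script score
recovery as "all true variables selected, with refit coefficients within
2 SE of truth" rather than exact set equality).

## The synthetic cohort

No public recording of this paradigm exists, so validation rests on a
generator whose ground truth is analytic.

**Background.** Each channel is $1/f$ noise (exponent 1) restricted to the
0.2–45 Hz passband, scaled to 10 µV SD, built in the frequency domain from
independent complex Gaussian bins; posterior channels (O1, O2, P7, P8)
carry an extra 9–11 Hz rhythm at 3 µV SD. The choice is the minimal
spectrum that looks like resting EEG to the downstream stages; nothing in
the pipeline depends on its details.

**Designed coherence.** A designed effect fixes the band coherence of a
channel pair during one task. Both channels receive a shared band-limited
Gaussian source $S$ plus independent band noise of equal spectral density:
$x_i = a_i S + N_i$. Writing $r_i = a_i^2/(a_i^2+1)$ for the in-band power
fraction contributed by $S$, the theoretical band coherence is
$\gamma^2 = r_i r_j$, so an isolated pair with target $g$ uses
$r_i = r_j = \sqrt g$, i.e. $a = \sqrt{\sqrt g / (1-\sqrt g)}$ — for
$g = 0.25$, exactly unit mixing over unit noise. Where several designed
pairs share a channel in one (task, band) — the published contrast set has
an O1-centred star in answer-2 gamma and a shared FC6 in reading alpha — a
single source per connected component is used and the $r_c$ are solved on
the component's tree: the root (highest degree) takes
$r = \max_e \sqrt{g_e}$ and each child takes $g_e / r_{parent}$. This
reproduces the closed form for isolated pairs, attains every target in a
tree, and is rejected (with an error) for cyclic effect sets, whose targets
may be jointly infeasible. A side effect is a nonzero coherence between
two leaves of the same component; it is part of the designed model, not a
bug, and mimics the diffuse synchrony such patterns reflect in real data.

Injected band content replaces the background in that band; a 3 Hz guard
band around the injected band is cleared as well, because the Kaiser
window's mainlobe would otherwise leak independent background into the
band-edge bins and bias the realized coherence a few percent low. Targets
of exactly 1 are rejected (unattainable with nonzero noise), as are
duplicate entries for one (pair, band, task).

**Artifacts.** A configurable fraction (default 10%) of 1-second epochs
receive a 0.5-second raised-cosine transient, 500 µV peak — far above five
background SDs — on two random channels, emulating head/muscle movement.
Contaminated indices are returned as ground truth for detector tests.

**Behavior.** Performance and TLX (as fractions of their scales) are linear
in named normalized features plus Gaussian noise (default SD 0.05 and 0.04
of scale — small enough that coefficient recovery at n = 16 is feasible),
clipped to [0, 1]. The default performance model loads on three designed
connectivity contrasts so the groups separate to roughly 90% vs 50%, echoing
the published contrast; the default TLX model reuses the published model's
coefficients on features *without* designed group contrasts, so both groups
report similar load. Six TLX subscales are drawn around the intended total
and re-summed. Two raters' checklist ratings (0/1/2 on 10 weighted items)
derive from performance through item difficulties plus rater noise (SD 0.25
rating units; zero noise yields identical raters, hence ICC = 1).

**What the generator does not emulate** — and what passing tests therefore
do not establish about real recordings: volume conduction and reference
effects (which inflate neighbour coherence broadly), non-stationarity
across a segment, ocular/EMG artifacts with realistic spectra, per-subject
spectral idiosyncrasies, and any nonlinear coupling. The generator
validates the *estimators and the inference machinery*, not the
neurophysiology.

## Numerical choices

* Kaiser β = 8 (the window family is fixed by the acquisition description;
  β is not) — sidelobes below −60 dB suppress leakage between bands.
* 1-second epochs give a 1 Hz grid; epoch FFTs are shared between PSD and
  coherence, and band power is read off the cross-spectral Gram diagonal.
* Coherence needs ≥ 2 retained epochs (one epoch is identically coherent);
  PSD needs ≥ 1; both error with the participant and task named.
* Constant feature columns normalize to zero with a warning; a constant
  outcome screens out everything with a warning.
* Degenerate t-tests: zero pooled SE with equal means gives p = 1, with
  distinct means p = 0.
* Perfect rater agreement returns ICC = 1 with a degenerate interval.
* Seeds: every stochastic stage takes one; the pipeline fans a master seed
  out by fixed offsets (all below 2³¹), making a run bit-reproducible.

## Problem sizes used in the tests

The generator's defaults are the study conditions (two groups of 8, 256 Hz,
segments of 180/180/720/180 s, 10% artifacts). Estimator-calibration tests
run the full 180 one-second epochs the design implies. For the end-to-end
recovery experiments (50 effect replicates and 8 null replicates of a
16-participant cohort) the package's test suite shortens the segments to
60/60/120/60 s: recovery power at the published effect magnitudes is
insensitive to this (the between-group contrasts are an order of magnitude
larger than the estimator SD at either length), while the false-positive
level depends only on the test, not the segment length. Unit tests use
smaller sessions still. The acceptance script mirrors the same computations
at reduced replicate counts.

## Limitations

* The naive post-selection inference described above.
* Coherence is sensor-space and signed-direction-free; no phase-lag or
  source-space variants are provided.
* The "semi-automatic" manual element of real artifact screening is not
  reproducible; thresholds plus an override list stand in for it.
* Published group-level EEG numbers from the motivating study cannot be
  reproduced exactly without its raw data (available only on request); the
  package instead recomputes its summary-level statistics exactly and
  validates everything else against synthetic ground truth.
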