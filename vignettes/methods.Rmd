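---
title: "Automated quality rating of intracellular recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated quality rating of intracellular recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysqc)
```

## The problem

Sharp-electrode intracellular recordings vary widely in quality: electrode
seals drift, cells deteriorate, artefacts intrude.  Before analysis an
electrophysiologist rates each ~5 s trace as *good*, *intermediate* or *bad*
— a slow, subjective step prone to selection bias.  `ephysqc` automates the
rating: a rule-based detector finds spikes, sixteen summary features encode
each trace, and a linear support vector machine (SVM) learns the expert's
judgement.  An exhaustive *wrapper* search over feature subsets finds the
informative features, and a two-stage leave-one-out procedure estimates
deployed performance without wrapper selection bias.

## Spike detection

The voltage trace $V(t)$ (mV, after gain correction) is smoothed with a
centred moving average of 3 ms; the half-width in samples is
$L = \mathrm{round}(1.5\,\mathrm{ms} \cdot f_s/1000)$ and windows shrink at
the trace edges.  Detection operates on the forward-difference derivative of
the filtered trace, in mV/ms.  Thresholds adapt to each recording:
$\theta_{up} = 3 P_{80}$ and $\theta_{down} = 3 P_{20}$ of all observed
derivative values (linear-interpolation percentiles throughout the package).
A candidate spike needs a run of 3 consecutive derivatives above
$\theta_{up}$ and, within $t_{spike,max} = 3$ ms, a run of 3 consecutive
derivatives below $\theta_{down}$.

Two numerical choices deserve note:

* **Where the 3 ms window starts.** A centred moving average of window $W$
  smears the rising lobe of the derivative over $W$ plus the upstroke
  duration, so for any realistic spike the first super-threshold sample
  precedes the first sub-threshold sample by *more* than $W = 3$ ms.  The
  rise-to-fall gap is therefore measured from the **end** of the rising run:
  the falling run must begin within 3 ms after it.  With the window anchored
  at the first up-crossing instead, a clean synthetic train yields zero
  detections (the gap sits at 31–32 samples against a 30-sample window at
  10 kHz) — that reading cannot be what a working detector does.
* **Degenerate thresholds.** On a noiseless trace the derivative is exactly
  zero between spikes, so $P_{80} = 0$ and $\theta_{up} = 0$.  Spikes are
  still perfectly detectable with strict (`>`) comparisons, so a trace is
  flagged undetectable only when the thresholds have the *wrong sign*
  ($\theta_{up} < 0$ or $\theta_{down} > 0$, a monotone drift) or the
  derivative is identically zero.

Each candidate is characterised on the **raw** trace: the maximum between
onset and offset defines the spike time; the local baseline is the mean over
$[-6,-3] \cup [+3,+6]$ ms around it; height is max minus baseline; width is
the distance between the nearest samples on each side that fall below
baseline plus half the height.  Extreme slopes are read from the
filtered-trace derivative.  Two eligibility rules then apply: (i) the trace
must dip below half height within 3 ms on both sides (rejecting step
artefacts), and (ii) the height must exceed half the 95th percentile of all
candidate heights in the trace (rejecting small secondary events), computed
in a first pass over all candidates.

## The sixteen features

Per recording: mean and coefficient of variation of spike height and width
(f1–f4); mean and standard deviation of the filtered potential trimmed to
its own 5th–95th percentile range (f5–f6); mean and standard deviation of
the short-timescale noise (f7–f8); ordinary-least-squares drifts of height,
width and noise versus time, per second (f9–f11); minimal inter-spike
interval in seconds (f12); means and standard deviations of the per-spike
extreme slopes (f13–f16).  The short-timescale noise at $t$ is the RMS
deviation of the raw from the filtered trace over a window of one filter
half-width either side,
$n(t) = \sqrt{\sum_{|t'-t| \le L} (V(t') - V_{avg}(t'))^2 / (2L+1)}$,
undefined within ±3 ms of any accepted spike (two maximal spike widths in
total) and at the trace edges where the window does not fit.

Conventions the source material leaves open, fixed here once: all standard
deviations are population ($\div N$); drifts are per second; percentiles use
linear interpolation; widths use the raw trace.  Degenerate traces (fewer
than two accepted spikes) take fill values — spike-dependent means, CVs and
drifts 0, minimal ISI equal to the trace duration — keeping every vector
finite and far from the "good" cluster.

## Classifier and cross-validation

A linear SVM with cost $C = 512$; multiclass problems use one-vs-one voting
(the convention of the LIBSVM lineage), with pairwise-vote ties resolved by
the summed signed decision values, then the lower class index.  Because no
SVM library is available in the target environment — and because the
classifier is the heart of the method — the solver is implemented in the
package: dual coordinate descent for the L2-regularised L1-loss problem with
random coordinate permutations and active-set shrinking, the standard
algorithm for this model family.  The learning-iteration cap of $10^4$
coordinate steps per pairwise problem mirrors the source procedure (which
reports that capping produced no discernible difference); the stopping
tolerance on the projected-gradient spread is 0.1, the customary default.
The permutation RNG is internal and fixed, so every fit is bit-reproducible.
Features are z-scored with training-fold statistics only (population SD,
zero-variance guard); at $C = 512$ a linear SVM is strongly scale-sensitive,
so standardisation inside every fold matters.

Cross-validation: 10 folds from a uniformly random permutation, every
recording left out exactly once per repeat, 50 repeats at full scale
(reduced to 5 in desk-scale runs), fraction correct pooled over folds and
averaged over repeats.  Splits are unstratified by default (a stratified
mode exists).

## Wrapper feature selection

All $2^{16} - 1 = 65535$ non-empty feature subsets are evaluated by repeated
cross-validation, grouped by subset size; per size the best, worst, median
and *top10* performance are recorded.  The top10 group holds the 10 best
subsets, or the best 10% when fewer than 100 exist, but always at least one:
$m = \min(10, \max(1, \lfloor 0.1 N \rfloor))$.  Ties in mean CV fraction
break by the canonical lexicographic rank of the subset (the `combn`
order), making the search deterministic end to end.  Subsets are named
`"<size>-<rank>"`, e.g. `6-2133`.

## Bias-free evaluation

Reporting the best wrapper result overstates deployed performance: with
65,535 comparisons, some subsets win by luck of the splits.  The two-stage
leave-one-out procedure removes this bias.  For each recording: leave it
out; run the full wrapper with leave-one-out CV on the remaining $n-1$
(10-fold at desk scale); take the $m = 10$ best subsets (by default
regardless of size, ties to smaller size then lower rank); train the 10
classifiers on all $n-1$; predict the held-out recording individually and by
majority vote (vote ties go to the best-ranked member).  The held-out
recording influences neither feature choice nor training — the package
records the inner training ids per fold so tests can verify this.  The
per-recording fraction of correct member predictions feeds a consistency
histogram (10 bins, 0–100%).

A caveat the package's own null experiments expose: on label-shuffled data
the held-out score is *near* but not exactly at the proportional chance rate
$\sum_i p_i^2$.  Max-margin classifiers trained on shuffled labels
over-predict the majority class, pulling the null score from the
proportional rate toward the majority rate ($\approx$ 54.6% for the default
100/54/29 composition); with balanced classes the opposite, a small
leave-one-out anti-bias, appears (the held-out class is always
under-represented in training).  Measured on the default corpus the gap is
about +2 to +9 points depending on the shuffle, straddling a ±5-point band.

## The synthetic corpus

The generator emulates sharp-electrode recordings: ~5 s at 10 kHz, a
stimulus 1.5 s after onset for 0.5 s that multiplies the firing rate.  Spike
times follow a renewal process — exponential inter-spike intervals shifted
by the refractory period, with the exponential mean set so the overall mean
rate equals the profile rate.  Each spike is a double-exponential bump
(decay time constant twice the rise), rescaled so its half-height width
equals the per-spike drawn width and its peak the drawn height.  Gaussian
noise, linear drifts of baseline, height and noise amplitude, and
step/transient artefacts are superimposed.  Everything is seeded and
bit-reproducible, and the ground truth (peak times, heights, widths,
artefact times) is returned with each trace.

Default class profiles state the world the tests run in: *good* — 25 mV
spikes (CV 0.10), 1.8 ms wide, 8 Hz, noise SD 0.3 mV, stable baseline at
−62 mV; *intermediate* — 15 mV (CV 0.25), 2.0 ms, 6 Hz, noise 0.9 mV,
mild height/noise/baseline drifts, occasional 4 mV steps; *bad* — sparse
8 mV spikes (CV 0.5), noise 2 mV, strong baseline drift, frequent large
step and transient artefacts.  Spike widths sit in the 1–2 ms range typical
of insect central neurons; rates and noise levels were chosen once as
plausible for pheromone-responsive antennal-lobe recordings and not
revisited.  Three named "bad" archetypes (artefact without spikes, unstable
baseline, few large spikes with small secondary events) are available for
regression tests.

What a green test on this corpus does **not** establish: the synthetic
classes are cleaner than real expert-labelled data (the full pipeline
separates them almost perfectly, where the source data allowed ~78%
three-class accuracy), there are no plateau potentials, current-injection
artefacts, 50 Hz hum or bursting, and the expert's implicit criteria beyond
these failure modes are not modelled.  Green means the machinery —
detection, features, selection, evaluation — is correct, not that any
particular accuracy transfers to real recordings.

For validating the wrapper itself a feature-space generator plants three
informative features (simplex-arranged class centroids, separation 2.5 SD)
among thirteen pure-noise features; the best size-3 subset should be the
planted triple.

## Scale reductions

The full wrapper (65,535 subsets × 50 repeats) and the full two-stage
procedure are cluster-scale computations (days of CPU in the original
setting).  Tests and the acceptance script run the sanctioned desk-scale
versions: 5 CV repeats, subset sizes restricted (size 3 for the planted
check, sizes 1–2 in the two-stage inner wrapper), and 10-fold rather than
leave-one-out inner CV.  All full-scale settings remain available through
function arguments.

## Known limitations

* The solver's iteration cap makes very large, ill-conditioned fits
  approximate; this mirrors the stated procedure but means weight vectors
  are not the exact dual optimum when the cap binds.
* `read_trace` handles the package's plain-text formats only; proprietary
  acquisition formats are out of scope by design.
* The two-stage procedure is $O(n \cdot \text{subsets} \cdot \text{folds})$
  SVM fits; full scale is a cluster job, not a laptop one.
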