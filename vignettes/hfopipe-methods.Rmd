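---
title: "Methods: two-step HFO detection and classification on energy features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step HFO detection and classification on energy features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High-frequency oscillations (HFOs) are brief oscillatory events in
intracranial EEG between 80 and 500 Hz, used as biomarkers of
epileptogenic tissue. `hfopipe` implements a two-step machine-learning
procedure over fixed-window energy features: step 1 separates segments
containing an HFO from background segments; step 2 assigns HFO segments
to one of three classes — ripples (R, 80–250 Hz), fast ripples (FR,
250–500 Hz) and fast ripples co-occurring with ripples (FRonR), a class
kept separate because co-occurrence localizes the seizure onset zone
better than either event type alone. This vignette documents the model,
its parameters, and every place where the design was genuinely open.

## Segmentation, filtering and features

Recordings are filtered into three bands — ripple (80–250 Hz), fast
ripple (250–500 Hz) and overall HFO (80–500 Hz) — and cut into
consecutive non-overlapping windows of 10, 50 or 100 ms (half-open
sample intervals; a trailing partial window is dropped). Four energy
features are computed per band and window, twelve per segment:

* line length: mean absolute first difference,
  $\frac{1}{N-1}\sum_{n}|x_{n+1}-x_n|$;
* short-time energy: $\frac{1}{N}\sum_n x_n^2$;
* RMS: $\sqrt{\frac{1}{N}\sum_n x_n^2}$ (so $\mathrm{rms}^2$ equals the
  short-time energy, an identity the tests assert row-wise);
* mean Teager energy:
  $\frac{1}{N-2}\sum_{n=2}^{N-1}(x_n^2 - x_{n-1}x_{n+1})$, which for a
  sinusoid $A\sin(\omega n)$ equals $A^2\sin^2\omega$ per sample — an
  instantaneous amplitude-times-frequency tracker.

All four are normalized by window length (means, not sums) so values are
comparable across the 10/50/100 ms conditions; the classical source
definitions differ on this point and classifier results are invariant to
the per-condition rescaling once features are standardized.

**Filter realization.** The band-pass is a linear-phase Hamming-window
FIR (order ≈ 330 at 2000 Hz, one-pass transition ≈ 20 Hz) applied
forward–backward through the frequency domain (the spectrum is
multiplied by $|H(f)|^2$), i.e. exact zero-phase filtering: band-filtered
events keep their annotated timing, which matters because segment labels
come from the unfiltered time axis. The one-pass design meets < 1 dB
pass-band ripple and ≥ 40 dB stop-band attenuation 20 Hz outside each
band edge; the two-pass application exceeds both. Circular wrap-around
affects only about one filter order at the record boundaries, negligible
for multi-second recordings.

**Labeling rule.** A segment takes the class of the ground-truth event
with which its temporal overlap fraction is maximal, provided that
fraction is at least 0.5; otherwise it is `noHFO`. Ties break by the
precedence FRonR > FR > R (the rarer, more specific class wins). The
0.5 threshold and the precedence are package choices — the source
protocol states only that ground-truth marks label the segments.

## The synthetic generator

Real annotated iEEG of this kind is not redistributable, so the package
ships a seeded generator that emulates the statistical structure the
pipeline assumes: 2000 Hz sampling, 5-minute interictal records,
4 channels, segment-level HFO prevalence below 10%, and a ~90% ripple
share among events. Its components:

* **Background**: $1/f^{\alpha}$ Gaussian noise (default $\alpha = 1$)
  scaled to a broadband RMS of 25 (µV scale — a realistic interictal
  amplitude; only ratios matter downstream), plus biphasic sharp
  transients (20–70 ms, 5× background RMS) at 1/min/channel as the
  classical source of false HFOs.
* **Events**: per channel a homogeneous Poisson process at
  6 events/min; class drawn from the mix 0.90/0.05/0.05 (R/FR/FRonR —
  the FR-vs-FRonR split of the non-ripple 10% is not dictated by the
  protocol and is configurable); overlapping placements are rejected and
  redrawn. Durations are truncated normal — R and FRonR:
  mean 96.2, sd 45.5 ms on [30, 300]; FR: mean 40.6, sd 26.7 ms on
  [10, 150] (the 10 ms lower bound reflects the shortest reported fast
  ripples). The parent location is calibrated by root finding so the
  *truncated* mean equals the quoted mean: truncating a normal located at
  the target mean would shift the sample mean up by ~7 ms, and the quoted
  values are observed moments, so the calibrated form is the faithful
  emulation.
* **Waveforms**: windowed sinusoids under a Tukey (tapered-cosine)
  envelope with a 5% cosine ramp at each edge (`edge_taper = 0.1`;
  setting 1.0 gives a Hann envelope). The envelope is deliberately
  near-flat: ground-truth marks delimit where an oscillation is
  *visible*, so an envelope that decays over most of the marked interval
  would make the annotation mislabel its own edges — with a full Hann
  envelope, segments that the ≥ 50%-overlap rule labels HFO carry almost
  no in-band energy and no detector can recover them. Center
  frequencies are drawn uniformly inside the nominal band with an edge
  margin of $\max(10, 2/\text{duration})$ Hz so the tone's main lobe
  stays inside its band (containment by construction, not merely up to
  leakage). An FRonR event is the sum of a ripple waveform and a
  fast-ripple waveform spanning the same support: a mark labeled FRonR
  asserts co-occurrence over the marked interval, so segments cut from
  it must carry both bands' signatures.
* **Amplitude**: each event's peak in-band amplitude equals
  `event_snr` (default 3) times the background RMS measured in the
  event's own band on the same channel.

What the generator does **not** emulate: physiologically detailed HFO
morphology (spectral chirps, asymmetric envelopes), ictal activity,
artifact channels, inter-channel correlation, and non-stationary
background. Tests passing on this generator therefore demonstrate that
the pipeline recovers its assumed statistical structure — not clinical
performance on hospital recordings.

## Step 1: balanced binary detection

HFO segments are rare (< 10%), so the negative class is randomly
undersampled to the positive count (all positives kept). 30% of the
balanced table, stratified, is held out for hyperparameter tuning; the
remaining 70% is evaluated by stratified 5-fold cross-validation. Five
families are compared with the grids:

| family | grid |
|---|---|
| LDA | none (fitted without optimization) |
| logistic regression | L2 penalty strength, 13 points log-spaced over exponents −3…3 |
| linear SVM | cost, same 13-point log grid |
| KNN | k ∈ 1…20 |
| random forest | trees {100, 200} × max depth {5, 10, 20} × min samples to split {2, 5, 10} × min samples per leaf {1, 2, 4} |

Tuning scores each candidate by mean AUC under an internal stratified
3-fold CV on the holdout (a single holdout fit would be noisier; the
protocol says only that the 30% served hyperparameter optimization).
Grids are ordered simplest-first (heavier regularization, larger k,
smaller forests) so exact score ties resolve to the simpler model.
Within each CV fold, features are z-scored with training-fold statistics
before fitting; sensitivity and specificity use a 0.5 threshold on the
positive-class probability, AUC uses the continuous score with a fixed
direction (chance-level scores give ≈ 0.5, never auto-flipped).
Learning curves rerun the chosen setting at fixed subsample sizes under
10-fold CV, reporting train/validation AUC and wall-clock fit time (fit
time is reported, never asserted). The whole step is within-subject,
mirroring the per-patient protocol.

## Step 2: three-class classification with ADASYN

On ground-truth HFO segments at 10 ms, ~90% are ripples, so the minority
classes are oversampled with ADASYN: for minority count $m_s$ and
majority count $m_l$, $G = (m_l - m_s)\beta$ synthetics are allocated to
minority points proportionally to $\Delta_i/K$ — the fraction of
non-minority points among each point's K nearest neighbors (Euclidean on
z-scored features) — and each synthetic is
$x_i + \lambda(x_z - x_i)$, $\lambda \sim U(0,1)$, with $x_z$ one of the
K nearest minority neighbors. Defaults K = 5 (the algorithm's canonical
setting), $\beta = 1$. The multiclass extension is one-vs-rest per
minority class against the majority count.

ADASYN runs **inside each training fold only**. Oversampling before the
split leaks interpolated copies of evaluation rows into training and
inflates metrics; because the protocol's order of operations is
ambiguous, the leak-free order is the default and the leaky order is
available behind the explicit flag `adasyn_before_split = TRUE` for
comparison. Synthetic rows carry a `synthetic` flag and never enter an
evaluation fold. Per-class sensitivity and specificity are one-vs-rest
from each fold's 3×3 confusion matrix.

A caveat established while validating this step on the generator: at
`event_snr = 3`, a fast ripple riding a chance ripple-band background
surge is feature-identical to an FRonR with a weak ripple component, and
half-coverage edge windows of short FR events sit inside other classes'
background tails. With the default event rates a 4-channel 5-minute
subject yields only ~15–40 FR segments, so FR sensitivity is both
information- and sample-limited (typically 0.6–0.9 across seeds while
all specificities exceed 0.95). The package reports what the data
support rather than tuning the generator to flatter numbers.

## Rank-based comparison suite

Window lengths and algorithms are compared across subjects with the
Friedman test (per-row average ranks, tie-corrected statistic, p from
$\chi^2_{k-1}$; the implementation matches `stats::friedman.test` to
machine precision, which the tests use as an independent reference).
Post-hocs:

* **Nemenyi**: critical difference
  $q_\alpha(k)\sqrt{k(k+1)/(6N)}$ with $q_\alpha(k)$ from the
  studentized-range distribution at infinite df divided by $\sqrt2$
  (computed, not tabulated) — used for the window-effect comparisons;
* **pairwise z-tests** with Holm (step-down) or Bergmann–Hommel
  correction — the latter enumerates all exhaustive hypothesis sets via
  set partitions of the conditions (Bell-number growth; supported for
  k ≤ 6, which covers five algorithms) and is the more powerful choice
  used for the algorithm-effect comparison.

Significance graphs connect conditions that are **not** significantly
different at $\alpha$ (default 0.05, also applied to post-hocs; the
protocol states $\alpha$ only for the Friedman test).

## Pipeline, seeds and problem sizes

`run_full()` drives simulate → extract → detect → classify → compare
from one validated YAML-dialect config (unknown keys are errors). One
master seed derives every stage seed via a seeded draw, so reruns are
byte-identical in their discrete outputs; the run manifest records the
config hash, derived seeds and every chosen hyperparameter. Learning
curves at the protocol's sizes (720/1440/2520/3240) are only feasible
when the balanced development set is large enough; `run_full()` drops
infeasible sizes with a logged notice while `learning_curve()` itself
treats them as errors. The test suite exercises the end-to-end run on
three default 5-minute subjects with the two fast families (LDA, KNN)
and all three windows — sizes chosen as a practical regression surface;
the full five-family run is the same code path.

## Known limitations

* EDF support is a minimal single-rate reader/writer (16-bit precision,
  1-second records); multi-rate files are rejected by design.
* The brute-force KNN is exact but $O(n^2)$ in distance computations,
  appropriate for the few thousand segments per subject used here.
* Step-2 minority metrics on default-sized synthetic subjects are
  noisy for the reasons given above; cross-subject transfer, artifact
  classes and physiological-vs-pathological discrimination are out of
  scope.
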