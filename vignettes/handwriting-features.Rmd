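---
title: "Handwriting kinematics: the feature model, pipeline and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handwriting kinematics: the feature model, pipeline and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The data model

A recording is an ordered sequence of pen samples $(x_i, y_i, z_i, o_i,
t_i)$: tablet coordinates and pressure in abstract device units, a
binary pen state ($o_i = 1$ on paper, $o_i = 0$ in air), and a
millisecond timestamp. Coordinates are never converted to millimetres —
tablet resolution varies by device and every descriptor is either
unit-free or reported in device units. Timestamps are converted to
seconds wherever a rate is formed. A *stroke* is a maximal run of
on-paper samples; an in-air segment is a maximal run of in-air samples.
A recording with zero samples is a first-class object (an *empty
recording*): it represents a task a subject did not complete, flows
through the census, and yields an all-NA feature vector.

Conventions that the formulas do not themselves fix, chosen once and
used everywhere:

* **Time attribution.** The interval $[t_i, t_{i+1})$ belongs to the
  pen state of sample $i$, so air time and paper time partition total
  time exactly.
* **Duplicate timestamps.** Tablets occasionally emit two samples with
  one timestamp. Such pairs stay in the data (they carry spatial
  information for displacement and entropy descriptors) but are skipped
  by every rate: speeds are formed only on intervals with $dt > 0$, and
  within-segment derivative chains drop the second sample of a
  duplicate pair.
* **Standard deviations** are sample ($n-1$) standard deviations
  throughout, matching the explicit $1/(m-1)$ and $1/(n-1)$ of the
  speed- and pressure-variability definitions.
* **Degenerate inputs** produce NA, never a silent zero: a quantity
  that needs two points is NA with fewer; a signal-to-noise ratio with
  zero variability is NA rather than infinite, so downstream imputation
  treats every undefined cell uniformly.

## The 48 descriptors

The per-task block consists of 18 baseline descriptors and 30 extended
ones, in a fixed canonical order (`feature_names()`).

**Baseline block.** Total/air/paper time; mean speed, mean absolute
acceleration and jerk, separately over on-paper and in-air segments
(derivatives never cross a pen lift; acceleration divides a speed
difference by the later interval's time step); on-paper pressure mean
and variance; mean relative tremor on paper, in air, and their mean;
pen-down count; coordinate extents; and a dispersion index. Two of
these have no universally fixed formula, so the package states its
convention and exposes it as configuration:

* **Tremor (GMRT family)** is the mean absolute turning angle in
  degrees between successive displacement vectors, pooled over all
  qualifying segments (at least three points and two nonzero
  displacements). Turning angles are rotation-invariant and rise with
  oscillatory direction changes, which is the behaviour the descriptor
  is meant to capture. `gmrt.convention` is a config key so a
  bit-compatible alternative can be swapped in; no attempt is made to
  match the published baseline CSVs bit-for-bit.
* **Dispersion index** is the occupied-cell fraction of a $G \times G$
  grid (default $G = 8$, key `di.grid`) over the on-paper bounding box,
  NA when fewer than two distinct pen positions exist.

**Extended block.** Mean azimuth uses the *two-quadrant* angle
$\arctan(\Delta y / \Delta x) \cdot 180/\pi \in (-90°, 90°)$ averaged
over all $n-1$ intervals, with vertical steps contributing
$\mathrm{sign}(\Delta y)\cdot 90°$; a config flag enables four-quadrant
angles. (The printed form of this average carries a $1/n$ prefactor
over $n-1$ terms; the package uses the true mean over intervals.)
Mean slope averages $\Delta y/\Delta x$ over intervals with
$\Delta x \neq 0$. Displacements are path-length sums. Stroke-geometry
descriptors use temporally consecutive stroke pairs; stroke
height/width compare each stroke's start with the first in-air sample
after it, and strokes with no following air point (a recording ending
on paper) are excluded — NA if none qualifies.

Entropies deserve their own paragraph because the symbolization is the
whole question. Tablet coordinates are *discrete device units*, so the
coordinate entropies (Shannon and Rényi $\alpha \in \{2,3\}$) count
exact values: $p(v) = \mathrm{count}(v)/n$. This makes them sensitive
to the number and balance of distinct pen positions and — by
construction — invariant under translation (a constant shift permutes
symbols without changing counts). The first-IMF entropy instead faces a
continuous-valued signal, so it uses a fixed-bin histogram (default 64
bins, key `entropy.bins`) over the IMF's range. Rényi entropies
decrease in $\alpha$ for any fixed distribution; the suite checks
$H_1 \ge H_2 \ge H_3$ on every generated trajectory.

Energy descriptors: conventional energy is $\sum s_i^2$ of the raw
coordinate signal; the Teager–Kaiser operator
$\Psi_i = s_i^2 - s_{i-1}s_{i+1}$ is summed over interior samples (a
sum, not a mean, matching the defining formulas). Note that
$\Psi$ of a linear ramp is the squared step, not zero — on a raw
coordinate signal the operator output rides on the trend, which is why
the tremor contrast in the generator shows up as a large *relative*
increase rather than a zero baseline. Signal-to-noise ratios are
$\mu/\sigma$ of the per-sample squared-coordinate series and of the
per-sample $\Psi$ series.

Speed variability is the sample SD of instantaneous speed over all
valid intervals of the whole recording; pressure variability is the
sample SD of pressure over *all* samples, in-air included, while the
baseline pressure mean/variance use on-paper samples only — the
asymmetry is deliberate and mirrors the definitions the block encodes.

## First-IMF sifting

No pre-packaged empirical mode decomposition was suitable, so the
package implements first-IMF sifting directly (`emd_first_imf()`),
with an independently written naive implementation serving as the
test oracle. The numerics:

* strict local extrema, with plateau runs of tied values (ubiquitous in
  integer coordinates) collapsed to a single extremum at the run's
  first sample;
* cubic-spline envelopes (natural splines) through maxima and minima,
  with the outermost two extrema mirrored about the signal ends to
  anchor the interpolation;
* the Cauchy-type criterion $\sum(h_{prev}-h)^2 / \sum h_{prev}^2 <
  0.2$ stops sifting, capped at 100 iterations (both configurable);
* monotone or constant signals, and signals shorter than four samples,
  have no defined decomposition: the IMF entropy is NA.

## Cohort matrices, missingness, normalization

`build_feature_matrix()` pivots per-recording vectors into a
subject × (task × 48) tibble with canonical task-major columns
`T{task:02d}_{FEATURE}`, so task- and feature-level tallies are
string-parsable. Missing cells stay NA until imputation.

The empty-recording policy is the one genuinely open design point: the
source protocol never states how uncompleted tasks enter the matrix.
The package imputes the per-column *median of the training partition*,
with all-missing columns falling back to zero. Min–max and z-score
normalizers likewise fit their statistics on designated rows only.
`run_nested_cv()` defaults to per-outer-fold fit scope — leakage-free —
and offers `fit_scope = "global"` and `selection_scope = "global"` to
mimic protocols that pre-normalize or pre-select on the full dataset
before cross-validation; the default is the defensible one, the global
switches exist for comparability.

## The model sweep

Per outer fold (10 stratified folds; 5 inner): impute and normalize on
training rows; fit the selector on training rows; tune each base
classifier by inner CV; refit on the full training fold; predict the
held-out fold; assemble ensembles. Every random draw derives from one
master seed, so a run is exactly reproducible.

Hyperparameter grids are compact, documented defaults: SVM
{linear, RBF} × cost {0.1, 1, 10}; random forest {100, 300} trees;
logistic regression as *ridge-penalized* logistic fits with
$\lambda \in \{10, 1, 0.1\}$ (the inverse of a $C \in \{0.1, 1, 10\}$
grid — after selection $p$ can approach $n$, where an unpenalized fit
is unstable); MLP with one hidden layer of {50, 100} units, weight
decay 0.1; boosted trees depth {3, 5} at learning rate 0.1, 100
rounds. The grids are deliberately desk-scale; they are arguments, not
constants.

The dynamic ensemble admits, per fold, the base models whose inner-CV
accuracy reaches the membership threshold — by default the mean of the
five inner scores, a self-calibrating cut that needs no tuning; if none
qualifies the single best model stands alone. The soft ensemble
averages member class probabilities with equal weights; the hard
ensemble majority-votes member labels over the same member set, gated
by a soft-score escalation threshold that defaults to always-on (both
thresholds are config keys, as the source protocol names but never
quantifies them). Tie-breaks are fixed: ranking ties resolve by
canonical column order, vote ties toward the class with the larger mean
soft probability, then toward the patient class.

Metrics are computed per fold and averaged: accuracy, macro-averaged F1
(the averaging flavour is a config key; macro is the default because on
a near-balanced cohort it tracks accuracy), sensitivity (patient
recall), specificity (healthy recall), and the SD of per-fold
accuracies — all in percent. A fold containing one truth class drops
out of the sensitivity or specificity mean rather than polluting it.

## Selection-frequency analyses

`tally_task_frequencies()` and `tally_feature_frequencies()` work from
the *best configuration per (strategy, selector)* — four configurations
per normalization strategy. This top-rule is a documented inference:
published feature-frequency tables step in quarters (consistent with
averaging counts over four selectors) and task-frequency columns sum to
roughly four times a typical selected-feature count. The rule is a
parameter, not a constant.

The task-reduction helper applies the stated exclusion rule (more than
10 empty recordings *and* low selection frequency, both cutoffs
arguments) and always reports the outcome next to the published
14-task constant, flagging divergence — the printed rule does not
reproduce the printed list (tasks with a dozen empty recordings were
retained, tasks with five were dropped), so the constant ships as data
and the rule as advisory.

The missingness/selection-frequency correlation is Pearson's $r$; on
the published per-task tables the unnormalized column reproduces the
published value (−0.231) exactly, which fixed the default column
choice.

## The synthetic cohort

The simulator exists so every stage is testable offline. It emulates:
two diagnostic classes differing in tremor amplitude (white jitter plus
an 8 Hz sinusoid — inside the physiological tremor band — both scaled
by one knob), multiplicative slowing, pressure noise, extra pen lifts
(Poisson), and class-skewed empty-recording probabilities. Class
defaults are fixed once: healthy tremor 0.5 units / speed scale 1 /
pressure SD 1 / 0.3 lifts / empty probability 0.025; patient tremor
3 / slowdown 1.5 / pressure SD 4 / 2 lifts / empty probability 0.045.
The empty probabilities match the per-class empirical rates of the
public 25-task cohort (54/2125 and 99/2225); the effect sizes are
chosen as a *strongly separated* cohort, the regime in which the
pipeline's calibration is asserted. Templates are fixed polyline sets
(lines, circles of two radii, letterform zigzags with small x
reversals, word-like multi-stroke sequences) traversed at constant
base speed and sampled at 50 Hz; coordinates are integer-rounded so
exact-value entropies behave as on a real tablet.

What the simulator does *not* model: biomechanically realistic
handwriting (no sigma-lognormal velocity profiles), letter identity,
fatigue or learning across tasks, device quantization beyond integer
rounding, or any resemblance to real subjects. Passing calibration
tests therefore demonstrates that the pipeline detects the *kinds* of
kinematic differences the descriptors target at realistic sample
sizes — not that it attains any particular accuracy on real cohorts.

## Validation problem sizes

The suite validates the extended descriptors against an independent
naive re-implementation on 100 random multi-stroke trajectories
(agreement to $10^{-9}$; $10^{-6}$ for the EMD-dependent entropy,
where the oracle runs its own independently coded sifting). The
end-to-end calibration uses the full synthetic cohort (89 + 85
subjects) on a 5-task subset — 240 features before selection — with the
full five-classifier roster for the strong-effect arm, and a
two-member (random forest + ridge-logistic) dynamic hard ensemble for
the ten permuted-label null runs; the null roster is smaller because
the null needs many repetitions and a chance-level check does not
benefit from the full grid. Null accuracies concentrate near 50%
(permuted-label cross-validation sits characteristically a point or
two below).

## Known limitations

* The baseline GMRT and dispersion-index conventions are this
  package's own (documented above); bit-compatibility with previously
  released baseline feature tables is explicitly out of scope.
* Exact-value entropies assume genuinely discrete coordinates; on
  floating-point input every value is its own symbol and the entropy
  saturates at $\log_2 n$.
* First-IMF sifting on short or nearly monotone signals is sensitive to
  boundary handling; the mirrored-extrema convention is standard but
  not unique, and IMF-dependent values should be compared only within
  one convention.
* The LR classifier is ridge-penalized; coefficients are not meant for
  inference.
* No scalers beyond min–max and z-score, and no automated optimal
  task-subset search — both named as future directions of the protocol
  this package operationalizes.
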