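---
title: "Repairing artifacted multichannel recordings by blockwise low-rank completion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing artifacted multichannel recordings by blockwise low-rank completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optrepair)
```

## The problem and the model

Multichannel electrophysiology (high-density EEG especially, but equally
MEG or LFP) is routinely corrupted by motion, ocular and muscle
artifacts.  In cohorts where long clean recordings are impossible --
infants, patients, the elderly -- rejecting every contaminated stretch
discards most of the data.  `optrepair` treats artifact-marked samples
as *missing entries of an approximately low-rank matrix* and
reconstructs them by matrix completion, exploiting the strong
spatiotemporal correlation of neural signals: scalp topographies are
generated by far fewer sources than sensors, so neural trajectories
occupy a low-dimensional subspace of channel space.

A continuous recording is a `C x T` matrix `D` (channels x samples,
microvolts).  After artifact marking, `D` is split into nonoverlapping,
stimulus-agnostic blocks `M` of `C x Tk` (the *completion epochs*,
unrelated to peristimulus trials).  Within a block, let `Omega(M)` be
the observed entries and its complement the corrupted ones.  We model

    M = X S t(Y) + Z,

with `X` (`C x r`) and `Y` (`Tk x r`) orthonormal, `S` (`r x r`), and
`Z` the off-subspace noise.  The factors are fit by minimizing the cost

    F(X, Y) = min_S || Omega(M) - Omega(X S t(Y)) ||_F,

i.e. the Frobenius norm of the misfit *over observed entries only*, the
core `S` being profiled out exactly (a linear least-squares problem in
its `r^2` entries).  The fitted low-rank model then supplies values for
every entry, including the corrupted ones.  Fitting factors per block,
rather than one subspace for the whole recording, lets the subspace
track slow nonstationarities: the algorithm samples local linear
(tangent) approximations of the nonlinear manifold on which the
trajectory evolves.

Completion is only identifiable under three assumptions: (1) the block
is well approximated at low rank, with energy spread across the factor
directions; (2) every row and column retains at least one observed
entry; (3) missing entries are spread out rather than adversarially
clustered.  Assumption 2 is checked explicitly (`infeasible_lines()`);
violating lines are excluded from the fit and reported irrecoverable
rather than guessed.  Assumption 3 fails for realistic bursty
artifacts, which is precisely why the package ships a surrogate
benchmarking framework to *measure* how accuracy degrades with artifact
severity instead of assuming a recovery guarantee.

## The optimizer

`complete_block()` proceeds in three stages.

1. **Trimmed spectral initialization.**  Corrupted entries are replaced
   by zeros; rows/columns with observed-entry counts above
   `degree_factor = 2` times the mean row/column count are blanked
   (over-represented lines would otherwise dominate the spectrum); the
   zero-filled matrix is rescaled by `(C * Tk) / |Omega|`, which makes
   it an unbiased estimate of the full block under uniform sampling,
   and its rank-`r` truncated SVD provides starting factors.  For
   heavily structured masks, trimming can be destructive (a few intact
   rows against many nearly-empty ones); if it would blank every
   observed entry the initialization falls back to the untrimmed
   block.  Singular-vector signs are fixed (largest-magnitude entry of
   each left vector positive) so factorizations are reproducible across
   platforms.
2. **Projected gradient descent.**  The Euclidean gradient of the
   squared cost at the current core is projected onto the tangent space
   of the orthonormal frames, a Barzilai-Borwein step guess is
   safeguarded by Armijo backtracking (halving, sufficient-decrease
   `1e-4`), factors are re-orthonormalized by QR after every step, and
   the core is re-solved exactly once per accepted step.  Because the
   line search only accepts sufficient decrease and re-solving the core
   can only lower the profiled cost, the accepted cost sequence is
   nonincreasing by construction -- a property the test suite asserts
   on every run.
3. **Alternating-least-squares polish.**  Steepest descent can crawl
   along ill-conditioned valleys of `F`.  After the gradient loop, the
   optimizer alternates exact row-wise refits of each factor's subspace
   given the other (each half-step is a closed-form masked least
   squares, so the cost again cannot increase) until the same relative
   tolerance is met.  On well-conditioned blocks this adds one or two
   cheap sweeps; on stalled blocks it closes the gap to what a generic
   quasi-Newton optimizer reaches on the same objective (the test suite
   compares both on small instances).

Convergence uses `tol = 1e-6` relative cost decrease with
`max_iter = 200` per phase, plus an absolute floor at `1e-10` of the
observed-data norm so that exactly-low-rank blocks terminate; blocks of
the sizes used here (at most 128 x 470) complete in fractions of a
second to a few seconds.  The core solver assembles the `r^2 x r^2`
normal equations directly (never the `|Omega| x r^2` design matrix) and
raises a "singular core system" error when the observed entries cannot
pin down the core, which callers treat like a completability violation.

### Choosing the rank

The rank is the one genuinely delicate hyperparameter, and its effect
differs by scope:

* Correlation over **all** entries saturates once `r` reaches the
  dominant signal dimensionality and stays flat for larger `r`
  (observed entries are always fit nearly perfectly).
* Correlation over **hidden** entries is maximized near the true signal
  rank.  When `r` exceeds it, the spare factor dimensions can fit
  "truncated" copies of channels that vanish exactly inside long gaps
  -- the observed cost cannot see the difference, and hidden-entry
  accuracy collapses.  Lower ranks reconstruct missing data better than
  higher ranks; higher ranks fit the observed data better.

Both modes from the literature are exposed: a fixed rank for all blocks
(`repair_config(rank = )`) and, in the trial-repair comparison
(`compare_erp_pipelines()`), a per-trial adaptive rank that keeps the
observed entries at least twice the factor-model degrees of freedom
`r (C + Tk - r)`, so heavily corrupted trials are completed at lower
rank.  The adaptive rule is deliberately conservative; the benchmark
module is the tool for calibrating a fixed rank on data like yours.

## The repair pipeline

`mark_artifacts()` implements three standard threshold rules: (a)
sample-to-sample jumps above 250 uV mark their two flanking samples;
(b) fast-minus-slow moving-average deviations above 150 uV (20 ms and
500 ms centered windows -- values separating transients from drifts at
250 Hz; both configurable); (c) entries more than 10 SD from the
overall voltage mean.  Manual interval annotations are OR-ed in after
rule-based marking, and the rejection fractions are evaluated on the
merged mask.  Channels with more than 70% bad samples are rejected for
the whole recording; timepoints bad on more than 75% of channels are
rejected for all channels; both comparisons are strict.  Peristimulus
trials with more than 50% corrupted entries are dropped.  All units are
microvolts; thresholds scale linearly if the caller declares another
unit.

`repair_recording()` epochs the (rejection-trimmed) recording into
`Tk = 120`-sample blocks by default, completes each feasible submatrix,
and writes back either the full low-rank model (`replace_observed =
TRUE`, the default: the model *regenerates* the whole block, which also
denoises observed samples) or only the corrupted entries
(`replace_observed = FALSE`, bitwise-preserving observed data).  A
remainder block shorter than `2 r` columns is merged into the previous
block to avoid degenerate least-squares systems.  Per-block failures
are reported, never fatal.

Filtering order matters: completion should run on the *unfiltered*
data, with the 0.5--20 Hz zero-phase band-pass
(`bandpass_recording()`, fourth-order Butterworth applied forwards and
backwards) afterwards.  Two effects stack: a power-line component is a
spatially coherent rank-one structure that helps rather than hurts the
fit, and filtering first smears high-amplitude artifact samples into
neighboring clean samples before the mask can protect them.  The test
suite asserts the ordering advantage on synthetic recordings with a
50 Hz common component and amplitude-corrupted entries.

## Surrogate benchmarking

Because severe artifacts violate the uniform-sampling assumption,
accuracy must be measured, not assumed.  The benchmark module mirrors
standard surrogate methodology: draw nonoverlapping chunks from (one or
several) recordings; chunks without corrupted entries form the *good*
library, the corruption patterns of the rest form the *bad* library
(`build_library()`); bad patterns are split into five equiprobable
severity classes by empirical quintiles (`quantile_classes()`);
overlaying a bad pattern on a good block (`make_surrogate()`) yields a
corrupted block whose ground truth is known.  `sweep_benchmark()` then
bootstraps (good, bad) pairs with replacement for every (block size,
severity class, rank) cell, completes, and records Pearson correlation
and relative Frobenius distance `||truth - est||_F / ||truth||_F` over
all, observed, and hidden entries.  Draws whose pattern leaves an
all-missing line (or a singular core system) are resampled up to a cap,
with counts recorded -- with realistic burst statistics a few percent
of draws are impossible to complete, and silently dropping them would
bias the severity classes.  Chance levels come from entry permutations
(`chance_level()`): the 95th percentile of truth-vs-permuted-truth
correlations and the 5th percentile of the corresponding distances.
All randomness flows from one seed through a per-cell counter, so any
cell is reproducible in isolation.

Library building samples *without* replacement (nonoverlapping chunks,
which is stricter than necessary but gives clean train/test semantics);
bootstrapping samples *with* replacement.  The Frobenius distance is
normalized by the truth norm; the normalization choice is recorded in
the output metadata by being part of the documented definition.

## The spherical-spline comparator

The conventional alternative repairs *channels*, not entries: every
channel containing an artifact is rebuilt entirely from the remaining
channels by spherical-spline interpolation on a unit-sphere montage
(stiffness `m = 4`, 7-term Legendre series, ridge `1e-5` -- the
published defaults of the method's reference implementation).  The
interpolation matrix solves the regularized spline system with the
constant-term constraint, so constants are reproduced exactly and the
map is linear.  Note that with a truncated series and ridge
regularization the kernel is not exactly reproducing: a bad channel
colocated with a good one receives an accurate *estimate* on smooth
fields but not a literal unit weight.  The comparator is purely
spatial -- it ignores temporal structure and replaces whole channels --
which is exactly the weakness the blockwise completion addresses, and
the paired benchmark (`spline_repair_block()` vs `complete_block()` on
identical surrogates) quantifies the difference.  An idealized
Fibonacci-lattice cap layout (`ideal_montage()`, synthetic, not a
vendor montage) supports tests and examples; real montages load from
`(label, x, y, z)` CSV.

## Downstream analyses

`preprocess_trials()` applies, per trial: baseline correction
(channel-wise mean of the baseline window subtracted), average
referencing, and normalization by global field power -- the
across-channel SD at each time point -- with an epsilon floor
(`1e-10` of the trial's largest GFP) guarding near-zero instants.  The
result is scale-invariant.  `erp()` averages a channel cluster, then
trials, with per-timepoint SEM; `grand_average()` adds the
across-subject level.  `between_trial_variability()` implements
event-related variability: at each time point in a 400--600 ms window
(the P400 neighborhood), trials are represented by their
across-channel vectors, pairwise distances `1 - r` are averaged over
unordered pairs and then over the window; pairs with undefined
correlation are skipped and counted.  Cohort scores are z-scored
against all analyzed subjects pooled (`zscore_cohort()`) before the
two-sided Wilcoxon rank-sum group comparison (`compare_groups()`).
The window-mean condition contrast is tested across subjects with a
one-sample F test (`contrast_f_test()`, `F = t^2` on `(1, n-1)`
degrees of freedom).

`compare_erp_pipelines()` packages the full paired comparison on a
synthetic cohort: the completion pipeline repairs every trial and
retains those whose *post-repair* corrupted fraction (irrecoverable
entries only) is at most 50%, spline-interpolating any channel that
remains corrupted so no artifact amplitude leaks into averages; the
conventional pipeline judges the 50% rule on the raw mask and rebuilds
every artifacted channel by spline interpolation.  Retention under
completion is a superset of retention under the conventional rule by
construction.

## What the synthetic generator emulates -- and what it does not

`generator_spec()` defaults describe a high-density infant-EEG-like
setting: 128 channels at 250 Hz, a rank-8 latent signal (half drifting
4--12 Hz oscillators, half band-limited smoothed noise) mixed at
~20 uV, 6 uV sensor noise (about 11% of the channel signal SD -- real
recordings carry a large non-low-rank component, which is why observed
hidden-entry accuracies in practice sit well below 1), and an optional
50 Hz common-mode line component (which replaces the last latent
source, keeping the noiseless rank exact).  Artifact masks are
dominated by movement-like bursts (`2e-3`/sample, geometric mean 100
samples) covering a random channel subset whose fraction is drawn from
a left-skewed Beta(0.5, 1.5) over 2--95% of the montage: most events
touch a few channels, rare ones are near-global.  Uniform speckle and
single-channel blips run at trace rates (`1e-6`), and all-channel
bursts (`1e-4`/sample) create the small fraction of genuinely
incompletable stretches that timepoint rejection and the sweep's
resampling absorb.  These rates were fixed once against three
qualitative targets a realistic fixture must meet: block severities
right-skewed with most bad blocks mildly corrupted and the top
quintile reaching tens of percent; artifact-free blocks common at
short block sizes and rare at the longest; and a corruption scope
large enough per event that hidden-entry correlations are measurable
(a correlation over a handful of entries is noise, whatever the
repair quality).  Corrupted entries receive high-amplitude junk
(`corrupt_recording()`, ~400 uV slow oscillation plus noise) so that
order-of-operations effects -- filtering smearing artifacts into clean
samples -- exist in the fixtures as they do in real data.

The trial generator builds each subject's trials as a shared evoked
trajectory plus per-trial ongoing low-rank activity, both normalized to
the zero-mean/unit-SD channel-vector space in which the variability
metric operates, mixed as `sqrt(1-d) * shared + sqrt(d) * ongoing`.
This makes the expected pairwise trial distance equal the group target
`d` directly, so a configured 2:1 group ratio is recoverable by the
analysis chain -- a parameter-recovery test of metric and generator
jointly.  The condition effect is a Gaussian-windowed bump on a channel
cluster inside 250--450 ms for one condition.

What passing tests on these fixtures *do* show: the completion
machinery recovers low-rank structure through realistic bursty masks,
degrades gracefully with severity, beats whole-channel spatial
interpolation when temporal structure exists, and preserves downstream
ERP/variability effects.  What they do *not* show: performance on
signals whose effective rank, nonstationarity or artifact morphology
differ materially from the generator -- real EEG has a continuous
singular spectrum rather than an exact rank cut-off, channel-dependent
noise, and artifacts correlated with the signal.  Benchmarks on a
surrogate library built from *your own* recordings (the intended use of
the benchmark module) are the meaningful calibration.

## Numerical choices and degenerate inputs

* Convergence: `tol = 1e-6` relative cost change, `max_iter = 200`,
  absolute floor `1e-10 * ||Omega(M)||_F`.
* Core solves raise a "singular core system" error instead of silently
  regularizing; the ALS polish uses a `1e-10` ridge purely for
  numerical stability of its inner refits.
* SVD sign ambiguity fixed by the largest-entry convention; QR
  retractions force positive diagonal in `R`.
* All-missing rows/columns: excluded from the fit, reported
  (`infeasible_rows`/`cols`, report column `status`), original values
  left untouched, mask left corrupted.
* Constant data: correlations over constant scopes are `NA`, never 0;
  zero GFP instants are floored and counted; zero-norm electrode
  positions are an error naming the channel.
* Severity ties in `quantile_classes()` are broken by stable order;
  fewer than `k` distinct severities flags the classes degenerate.
* The optimizer, generator and sweep are deterministic given their
  seeds; the completion core itself contains no randomness.

## Problem sizes used by the shipped tests

The package's own test and acceptance runs use desk-scale versions of
the study conditions, chosen to finish in minutes on one core while
leaving every qualitative contrast intact: 32--128 channels, 30 000
sample recordings (2 minutes at 250 Hz), libraries pooled over 4--8
synthetic subjects, 50 bootstrap iterations per cell (against 500 at
full scale), severity sweeps at `Tk = 120` and the rank sweep at
`Tk = 470`, and cohorts of 8--20 subjects per group.  The exact-recovery
check runs the full 128 x 120 rank-4 setting with 10% uniform
corruption.  Three measurement conventions are worth stating: severity
class medians are compared at the 0.01 resolution correlations are
conventionally reported (with 50 bootstrap draws per class, adjacent
medians differing by less are ties, not an ordering); the rank sweep at
the largest block size caps the optimizer at 100 iterations per block
as a compute budget (its all-entry medians converge well before that);
and grand-average peak latencies are read off a 20 ms smoothed curve,
as is standard for ERP latency estimation.  For the end-to-end ERP comparison the cohort uses
intentionally harsh trial corruption (about half the trials beyond the
50% rejection threshold before repair) because that is the regime in
which repair-based trial retention matters at all; with mild corruption
both pipelines trivially coincide.

## Known limitations

* Completion accuracy on hidden entries is intrinsically limited by
  assumption 3: long bursts concentrated in a channel leave little
  information to reconstruct from, and accuracy degrades with severity
  -- measured, not hidden, by the benchmark.
* The per-block optimum is local; the spectral initialization makes it
  reliable in practice but no global guarantee exists.
* `O(|Omega| r^2 + r^4 Tk)` per core solve means large ranks on long
  blocks are noticeably slower; the pipeline is offline, not
  streaming.
* The spline comparator uses an idealized spherical geometry; no
  realistic head shapes.
* Rank selection is the caller's responsibility; the adaptive per-trial
  rule is a heuristic, not an estimator of signal dimensionality.
* No incoherence regularization is applied to the factors: the plain
  observed-entry cost is always the objective.
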